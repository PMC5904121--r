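#' Hand-built E. coli core model for methanol-essentiality design
#'
#' A reduced stoichiometric model (~80 reactions) of Escherichia coli central
#' carbon metabolism built for growth-coupled methanol-assimilation design.
#' It reproduces the pathway topology that decides methanol essentiality on
#' gluconate: gluconate uptake and phosphorylation to 6-phosphogluconate,
#' the Entner-Doudoroff pathway (Edd/Eda), the oxidative pentose phosphate
#' branch (Zwf/Gnd) decarboxylating to ribulose 5-phosphate, the full
#' non-oxidative pentose phosphate pathway (RpiAB, Rpe, TktAB, TalAB,
#' reversible), upper and lower glycolysis with gluconeogenic bypasses, the
#' TCA cycle with both NAD-dependent malate dehydrogenase (maldh) and the
#' malate:quinone oxidoreductase alternative (mqo), the glyoxylate shunt,
#' anaplerosis (Ppc/Pck/malic enzymes), endogenous formaldehyde oxidation
#' (FrmA, formate dehydrogenase), a lumped nucleoside-salvage catabolism of
#' ribose 5-phosphate (deoB/deoC; the RuMP-cycle branch point towards PRPP
#' and deoxyribose 5-phosphate), lumped oxidative phosphorylation (P/O = 2
#' for NADH), transhydrogenase, and a lumped biomass reaction drawing the
#' canonical twelve-precursor demand with 59.81 mmol gCDW^-1 growth-associated
#' ATP. Uptake systems for the eight co-substrates screened in the design
#' (acetate, gluconate, glucose, glycerol, pyruvate, ribose, xylose,
#' succinate) are gene-associated so transporter knockouts can be screened.
#'
#' The base model does not contain the heterologous RuMP entry reactions;
#' add them with [add_rump_pathway()].
#'
#' Cofactor pairs (ATP/ADP, NAD(H), NADP(H)) carry `n_carbon = 0` and
#' acetyl-CoA counts only its acetyl carbons, so every internal reaction is
#' balanced for transferable backbone carbon (see [carbon_balance()]).
#'
#' @return A validated `metabolic_model`.
#' @examples
#' m <- core_model()
#' growth_on(m, "EX_glcn")
#' @export
core_model <- function() {
  mets <- local({
    m <- function(id, name, compartment, n_carbon)
      data.frame(id = id, name = name, compartment = compartment,
                 n_carbon = n_carbon, stringsAsFactors = FALSE)
    rbind(
      m("glcn_e", "D-gluconate (external)", "e", 6L),
      m("glc_e", "D-glucose (external)", "e", 6L),
      m("xyl_e", "D-xylose (external)", "e", 5L),
      m("rib_e", "D-ribose (external)", "e", 5L),
      m("glyc_e", "glycerol (external)", "e", 3L),
      m("pyr_e", "pyruvate (external)", "e", 3L),
      m("ac_e", "acetate (external)", "e", 2L),
      m("succ_e", "succinate (external)", "e", 4L),
      m("meoh_e", "methanol (external)", "e", 1L),
      m("for_e", "formate (external)", "e", 1L),
      m("co2_e", "CO2 (external)", "e", 1L),
      m("o2_e", "O2 (external)", "e", 0L),
      m("nh4_e", "ammonium (external)", "e", 0L),
      m("pi_e", "phosphate (external)", "e", 0L),
      m("h2o_e", "water (external)", "e", 0L),
      m("h_e", "proton (external)", "e", 0L),

      m("glcn_c", "D-gluconate", "c", 6L),
      m("g6p_c", "D-glucose 6-phosphate", "c", 6L),
      m("f6p_c", "D-fructose 6-phosphate", "c", 6L),
      m("fbp_c", "D-fructose 1,6-bisphosphate", "c", 6L),
      m("dhap_c", "dihydroxyacetone phosphate", "c", 3L),
      m("g3p_c", "glyceraldehyde 3-phosphate", "c", 3L),
      m("pg3_c", "3-phospho-D-glycerate", "c", 3L),
      m("pep_c", "phosphoenolpyruvate", "c", 3L),
      m("pyr_c", "pyruvate", "c", 3L),
      m("6pg_c", "6-phospho-D-gluconate", "c", 6L),
      m("kdpg_c", "2-keto-3-deoxy-6-phospho-D-gluconate", "c", 6L),
      m("ru5p_c", "D-ribulose 5-phosphate", "c", 5L),
      m("x5p_c", "D-xylulose 5-phosphate", "c", 5L),
      m("r5p_c", "D-ribose 5-phosphate", "c", 5L),
      m("s7p_c", "sedoheptulose 7-phosphate", "c", 7L),
      m("e4p_c", "D-erythrose 4-phosphate", "c", 4L),
      m("acald_c", "acetaldehyde", "c", 2L),
      m("accoa_c", "acetyl-CoA (acetyl carbons)", "c", 2L),
      m("cit_c", "citrate", "c", 6L),
      m("icit_c", "isocitrate", "c", 6L),
      m("akg_c", "2-oxoglutarate", "c", 5L),
      m("succ_c", "succinate", "c", 4L),
      m("fum_c", "fumarate", "c", 4L),
      m("mal_c", "L-malate", "c", 4L),
      m("oaa_c", "oxaloacetate", "c", 4L),
      m("glx_c", "glyoxylate", "c", 2L),
      m("kdo8p_e", "KDO 8-phosphate (LPS overflow, external)", "e", 8L),
      m("kdo8p_c", "KDO 8-phosphate", "c", 8L),
      m("dha_c", "dihydroxyacetone", "c", 3L),
      m("glyc_c", "glycerol", "c", 3L),
      m("glyc3p_c", "sn-glycerol 3-phosphate", "c", 3L),
      m("xyl_c", "D-xylose", "c", 5L),
      m("rib_c", "D-ribose", "c", 5L),
      m("ac_c", "acetate", "c", 2L),
      m("meoh_c", "methanol", "c", 1L),
      m("fald_c", "formaldehyde", "c", 1L),
      m("for_c", "formate", "c", 1L),
      m("co2_c", "CO2", "c", 1L),
      m("o2_c", "O2", "c", 0L),
      m("nh4_c", "ammonium", "c", 0L),
      m("pi_c", "phosphate", "c", 0L),
      m("h2o_c", "water", "c", 0L),
      m("h_c", "proton", "c", 0L),
      m("atp_c", "ATP (carrier)", "c", 0L),
      m("adp_c", "ADP (carrier)", "c", 0L),
      m("nad_c", "NAD+ (carrier)", "c", 0L),
      m("nadh_c", "NADH (carrier)", "c", 0L),
      m("nadp_c", "NADP+ (carrier)", "c", 0L),
      m("nadph_c", "NADPH (carrier)", "c", 0L))
  })

  rx <- function(id, name, stoich, rule = "", lb = 0, ub = 1000,
                 ex = FALSE) {
    list(id = id, name = name, stoich = stoich, lower_bound = lb,
         upper_bound = ub, gene_rule = rule, is_exchange = ex)
  }
  ex <- function(id, met, open_uptake = FALSE) {
    rx(id, paste("exchange:", met), setNames(-1, met),
       lb = if (open_uptake) -1000 else 0, ex = TRUE)
  }
  s <- function(...) {
    v <- c(...)
    stopifnot(!is.null(names(v)), all(nzchar(names(v))))
    v
  }

  rxns <- list(
    ## exchanges: carbon sources shipped closed to uptake, inorganics open
    ex("EX_glcn", "glcn_e"), ex("EX_glc", "glc_e"), ex("EX_xyl", "xyl_e"),
    ex("EX_rib", "rib_e"), ex("EX_glyc", "glyc_e"), ex("EX_pyr", "pyr_e"),
    ex("EX_ac", "ac_e"), ex("EX_succ", "succ_e"), ex("EX_meoh", "meoh_e"),
    ex("EX_for", "for_e"), ex("EX_co2", "co2_e"),
    ex("EX_kdo8p", "kdo8p_e"),
    ex("EX_o2", "o2_e", TRUE), ex("EX_nh4", "nh4_e", TRUE),
    ex("EX_pi", "pi_e", TRUE), ex("EX_h2o", "h2o_e", TRUE),
    ex("EX_h", "h_e", TRUE),

    ## substrate transport and activation
    rx("GLCNt", "gluconate transport (GntT/GntU)",
       s(glcn_e = -1, glcn_c = 1), "gntT or gntU"),
    rx("GNTK", "gluconokinase",
       s(glcn_c = -1, atp_c = -1, `6pg_c` = 1, adp_c = 1), "gntK"),
    rx("GLCpts", "glucose PTS uptake",
       s(glc_e = -1, pep_c = -1, g6p_c = 1, pyr_c = 1), "ptsG"),
    rx("XYLt", "xylose ABC transport",
       s(xyl_e = -1, atp_c = -1, h2o_c = -1, xyl_c = 1, adp_c = 1, pi_c = 1),
       "xylF and xylG and xylH"),
    rx("XYLK", "xylose isomerase + xylulokinase (lumped)",
       s(xyl_c = -1, atp_c = -1, x5p_c = 1, adp_c = 1), "xylA and xylB"),
    rx("RIBt", "ribose ABC transport",
       s(rib_e = -1, atp_c = -1, h2o_c = -1, rib_c = 1, adp_c = 1, pi_c = 1),
       "rbsA and rbsB and rbsC"),
    rx("RBK", "ribokinase",
       s(rib_c = -1, atp_c = -1, r5p_c = 1, adp_c = 1), "rbsK"),
    rx("GLYCt", "glycerol facilitated diffusion",
       s(glyc_e = -1, glyc_c = 1), "glpF", lb = -1000),
    rx("GLYK", "glycerol kinase",
       s(glyc_c = -1, atp_c = -1, glyc3p_c = 1, adp_c = 1), "glpK"),
    rx("G3PD", "glycerol-3-phosphate dehydrogenase (lumped)",
       s(glyc3p_c = -1, nad_c = -1, dhap_c = 1, nadh_c = 1), "glpD"),
    rx("GPSA", "glycerol-3-phosphate dehydrogenase (NADPH, biosynthetic)",
       s(dhap_c = -1, nadph_c = -1, glyc3p_c = 1, nadp_c = 1), "gpsA"),
    rx("G3PP", "glycerol-3-phosphate phosphatase",
       s(glyc3p_c = -1, h2o_c = -1, glyc_c = 1, pi_c = 1), "ybhA"),
    rx("GLYCDH", "glycerol dehydrogenase",
       s(glyc_c = -1, nad_c = -1, dha_c = 1, nadh_c = 1), "gldA"),
    rx("FSA", "fructose-6-phosphate aldolase",
       s(f6p_c = -1, dha_c = 1, g3p_c = 1), "fsaA or fsaB", lb = -1000),
    rx("PYRt", "pyruvate uptake", s(pyr_e = -1, pyr_c = 1), "btsT"),
    rx("ACt", "acetate uptake", s(ac_e = -1, ac_c = 1), "actP", lb = -1000),
    rx("ACS", "acetyl-CoA synthetase (lumped energetics)",
       s(ac_c = -1, atp_c = -1, accoa_c = 1, adp_c = 1, pi_c = 1), "acs"),
    rx("ACK", "phosphotransacetylase + acetate kinase (overflow route)",
       s(accoa_c = -1, adp_c = -1, pi_c = -1, ac_c = 1, atp_c = 1),
       "pta and ackA", lb = -1000),
    rx("SUCCt", "succinate uptake (DctA)", s(succ_e = -1, succ_c = 1),
       "dctA"),
    rx("MEOHt", "methanol diffusion", s(meoh_e = -1, meoh_c = 1),
       lb = -1000),
    rx("FORt", "formate transport (FocA)", s(for_c = -1, for_e = 1),
       "focA", lb = -1000),
    rx("O2t", "O2 diffusion", s(o2_e = -1, o2_c = 1), lb = -1000),
    rx("CO2t", "CO2 diffusion", s(co2_c = -1, co2_e = 1), lb = -1000),
    rx("H2Ot", "water transport", s(h2o_e = -1, h2o_c = 1), lb = -1000),
    rx("NH4t", "ammonium transport", s(nh4_e = -1, nh4_c = 1), "amtB",
       lb = -1000),
    rx("PIt", "phosphate transport", s(pi_e = -1, pi_c = 1),
       "pitA or pstS", lb = -1000),
    rx("Ht", "proton exchange (lumped)", s(h_c = -1, h_e = 1), lb = -1000),

    ## glycolysis / gluconeogenesis
    rx("PGI", "phosphoglucose isomerase", s(g6p_c = -1, f6p_c = 1), "pgi",
       lb = -1000),
    rx("PFK", "phosphofructokinase",
       s(f6p_c = -1, atp_c = -1, fbp_c = 1, adp_c = 1), "pfkA or pfkB"),
    rx("FBP", "fructose 1,6-bisphosphatase",
       s(fbp_c = -1, h2o_c = -1, f6p_c = 1, pi_c = 1), "fbp or glpX"),
    rx("FBA", "fructose-bisphosphate aldolase",
       s(fbp_c = -1, dhap_c = 1, g3p_c = 1), "fbaA or fbaB", lb = -1000),
    rx("TPI", "triose-phosphate isomerase", s(dhap_c = -1, g3p_c = 1),
       "tpiA", lb = -1000),
    rx("GAPD", "GAP dehydrogenase + phosphoglycerate kinase (lumped)",
       s(g3p_c = -1, nad_c = -1, adp_c = -1, pi_c = -1,
         pg3_c = 1, nadh_c = 1, atp_c = 1), "gapA and pgk", lb = -1000),
    rx("PGM", "phosphoglycerate mutase + enolase (lumped)",
       s(pg3_c = -1, pep_c = 1, h2o_c = 1), "(gpmA or gpmM) and eno",
       lb = -1000),
    rx("PYK", "pyruvate kinase",
       s(pep_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1), "pykA or pykF"),
    rx("PPS", "PEP synthetase (lumped energetics)",
       s(pyr_c = -1, atp_c = -2, h2o_c = -1, pep_c = 1, adp_c = 2, pi_c = 1),
       "ppsA"),
    rx("PDH", "pyruvate dehydrogenase",
       s(pyr_c = -1, nad_c = -1, accoa_c = 1, co2_c = 1, nadh_c = 1),
       "aceE and aceF and lpd"),

    ## pentose phosphate and Entner-Doudoroff pathways
    rx("ZWF", "G6P dehydrogenase + lactonase (lumped)",
       s(g6p_c = -1, nadp_c = -1, h2o_c = -1, `6pg_c` = 1, nadph_c = 1),
       "zwf"),
    rx("GND", "6-phosphogluconate dehydrogenase",
       s(`6pg_c` = -1, nadp_c = -1, ru5p_c = 1, co2_c = 1, nadph_c = 1),
       "gnd"),
    rx("EDD", "phosphogluconate dehydratase",
       s(`6pg_c` = -1, kdpg_c = 1, h2o_c = 1), "edd"),
    rx("EDA", "KDPG aldolase", s(kdpg_c = -1, pyr_c = 1, g3p_c = 1), "eda"),
    rx("RPI", "ribose-5-phosphate isomerase", s(ru5p_c = -1, r5p_c = 1),
       "rpiA or rpiB", lb = -1000),
    rx("RPE", "ribulose-5-phosphate 3-epimerase", s(ru5p_c = -1, x5p_c = 1),
       "rpe", lb = -1000),
    rx("TKT1", "transketolase (R5P + X5P)",
       s(x5p_c = -1, r5p_c = -1, g3p_c = 1, s7p_c = 1), "tktA or tktB",
       lb = -1000),
    rx("TAL", "transaldolase",
       s(g3p_c = -1, s7p_c = -1, e4p_c = 1, f6p_c = 1), "talA or talB",
       lb = -1000),
    rx("TKT2", "transketolase (E4P + X5P)",
       s(x5p_c = -1, e4p_c = -1, f6p_c = 1, g3p_c = 1), "tktA or tktB",
       lb = -1000),
    # lipopolysaccharide precursor synthesis: arabinose-5P isomerase +
    # KDO-8P synthase lumped. Drained by biomass (LPS is essential) and
    # sheddable as overflow; the only Rpi-independent exit from ribulose
    # 5-phosphate, as in the genome-scale models
    rx("KDOS", "KDO-8-phosphate synthesis (A5P isomerase + KDO8P synthase)",
       s(ru5p_c = -1, pep_c = -1, h2o_c = -1, kdo8p_c = 1, pi_c = 1),
       "kdsD and kdsA"),
    rx("KDOt", "KDO-8-phosphate overflow shedding",
       s(kdo8p_c = -1, kdo8p_e = 1)),
    # nucleoside-salvage pentose catabolism: phosphopentomutase branch of the
    # RuMP cycle via (deoxy)ribose phosphates to the deoC aldolase products
    rx("R5PCAT", "ribose-5-phosphate catabolism via nucleoside salvage (lumped)",
       s(r5p_c = -1, atp_c = -1, nadph_c = -1,
         g3p_c = 1, acald_c = 1, adp_c = 1, pi_c = 1, nadp_c = 1),
       "deoB and deoC"),
    rx("ACALD", "acetaldehyde dehydrogenase (acylating)",
       s(acald_c = -1, nad_c = -1, accoa_c = 1, nadh_c = 1),
       "adhE or mhpF"),

    ## TCA cycle, glyoxylate shunt, anaplerosis
    rx("CS", "citrate synthase",
       s(accoa_c = -1, oaa_c = -1, h2o_c = -1, cit_c = 1), "gltA"),
    rx("ACONT", "aconitase", s(cit_c = -1, icit_c = 1), "acnA or acnB",
       lb = -1000),
    rx("ICDH", "isocitrate dehydrogenase",
       s(icit_c = -1, nadp_c = -1, akg_c = 1, co2_c = 1, nadph_c = 1),
       "icd"),
    rx("AKGDH", "2-oxoglutarate dehydrogenase + succinyl-CoA synthetase",
       s(akg_c = -1, nad_c = -1, adp_c = -1, pi_c = -1,
         succ_c = 1, co2_c = 1, nadh_c = 1, atp_c = 1),
       "sucA and sucB and sucC and sucD and lpd"),
    rx("SUCDH", "succinate dehydrogenase + quinol oxidase (P/O 1)",
       s(succ_c = -1, o2_c = -0.5, adp_c = -1, pi_c = -1,
         fum_c = 1, atp_c = 1, h2o_c = 1),
       "sdhA and sdhB and sdhC and sdhD"),
    rx("FUM", "fumarase", s(fum_c = -1, h2o_c = -1, mal_c = 1),
       "fumA or fumB or fumC", lb = -1000),
    rx("MALDH", "malate dehydrogenase (NAD-dependent)",
       s(mal_c = -1, nad_c = -1, oaa_c = 1, nadh_c = 1), "maldh",
       lb = -1000),
    rx("MQO", "malate:quinone oxidoreductase + oxidase (P/O 1)",
       s(mal_c = -1, o2_c = -0.5, adp_c = -1, pi_c = -1,
         oaa_c = 1, atp_c = 1, h2o_c = 1), "mqo"),
    rx("ICL", "isocitrate lyase", s(icit_c = -1, succ_c = 1, glx_c = 1),
       "aceA"),
    rx("MALS", "malate synthase",
       s(glx_c = -1, accoa_c = -1, h2o_c = -1, mal_c = 1), "aceB"),
    rx("ME1", "malic enzyme (NAD)",
       s(mal_c = -1, nad_c = -1, pyr_c = 1, co2_c = 1, nadh_c = 1), "maeA"),
    rx("ME2", "malic enzyme (NADP)",
       s(mal_c = -1, nadp_c = -1, pyr_c = 1, co2_c = 1, nadph_c = 1),
       "maeB"),
    rx("PPC", "PEP carboxylase",
       s(pep_c = -1, co2_c = -1, h2o_c = -1, oaa_c = 1, pi_c = 1), "ppc"),
    rx("PCK", "PEP carboxykinase",
       s(oaa_c = -1, atp_c = -1, pep_c = 1, co2_c = 1, adp_c = 1), "pck"),

    ## endogenous formaldehyde/formate oxidation
    rx("FALDH", "formaldehyde dehydrogenase (glutathione pathway, lumped)",
       s(fald_c = -1, nad_c = -1, h2o_c = -1, for_c = 1, nadh_c = 1),
       "frmA"),
    rx("FDH", "formate dehydrogenase",
       s(for_c = -1, nad_c = -1, co2_c = 1, nadh_c = 1), "fdoG or fdhF"),

    ## oxidative phosphorylation, redox and energy housekeeping
    rx("NADHOX", "NADH oxidation + oxidative phosphorylation (P/O 2)",
       s(nadh_c = -1, o2_c = -0.5, adp_c = -2, pi_c = -2,
         nad_c = 1, atp_c = 2, h2o_c = 3),
       "(nuoA and cyoB) or (ndh and cydB)"),
    rx("THD", "transhydrogenase (PntAB/UdhA, lumped)",
       s(nadh_c = -1, nadp_c = -1, nad_c = 1, nadph_c = 1),
       "(pntA and pntB) or udhA", lb = -1000),
    rx("ATPM", "non-growth-associated maintenance",
       s(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1)),

    ## lumped biomass: canonical precursor demand, mmol gCDW^-1
    rx("BIOMASS", "biomass (core, 59.81 mmol ATP GAM)",
       s(g6p_c = -0.205, f6p_c = -0.071, r5p_c = -0.898, e4p_c = -0.361,
         g3p_c = -0.129, pg3_c = -1.496, pep_c = -0.519, pyr_c = -2.833,
         accoa_c = -3.747, oaa_c = -1.787, akg_c = -1.079,
         kdo8p_c = -0.02, atp_c = -59.81, nadph_c = -16, nh4_c = -10.2,
         h2o_c = -45, adp_c = 59.81, pi_c = 59.81, nadp_c = 16))
  )

  metabolic_model(mets, rxns, objective = "BIOMASS", id = "ecoli_core_rump")
}
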