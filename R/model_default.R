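#' Model configuration
#'
#' Selects which sub-modules of the endothelial signaling network are
#' assembled.  \code{"vegf"} is the VEGF/VEGFR2 receptor layer (VEGFR1 decoy,
#' NRP1, TSP1/CD47, trafficking), \code{"tie"} the angiopoietin/Tie receptor
#' layer (ligand multimers, Tie2 clustering, Tie1, VE-PTP, shedding, soluble
#' Tie2 trap), \code{"downstream"} the shared intracellular network
#' (Src, Axl, PI3K/Akt, PLCgamma/IP3/calcium, S1P, Raf/MEK/Erk, RhoA/mDia
#' Src sequestration, VE-cadherin, eNOS) and \code{"crosstalk"} the
#' VEGF-to-Tie coupling (VEGF-enhanced Tie2 shedding and S1P-driven
#' Weibel-Palade-body Ang2 release).
#'
#' @param modules Character vector of sub-modules to include.
#' @return A config list.
#' @export
model_config <- function(modules = c("vegf", "tie", "downstream",
                                     "crosstalk")) {
  known <- c("vegf", "tie", "downstream", "crosstalk")
  bad <- setdiff(modules, known)
  if (length(bad)) stop("unknown sub-module name(s): ",
                        paste(bad, collapse = ", "))
  if ("crosstalk" %in% modules &&
      !all(c("vegf", "tie", "downstream") %in% modules))
    stop("the crosstalk sub-module requires vegf, tie and downstream")
  list(modules = modules)
}

#' Baseline parameter set of the packaged model
#'
#' Units: first-order constants per minute, bimolecular constants per nM per
#' minute, abundances and Michaelis constants in nM (all species are expressed
#' as bath-equivalent concentrations), zeroth-order synthesis fluxes in nM per
#' minute.  Molecular weights (kDa) convert ligand doses given in ng/mL.
#' Entries tagged \code{"fixed"} are structural constants excluded from
#' calibration and sensitivity analysis.
#'
#' @return A [parameter_set()].
#' @export
default_parameters <- function() {
  fixed <- c("mw_vegf", "mw_ang1_tetramer", "mw_ang2_monomer",
             "ang2_frac_dimer", "ang2_frac_trimer", "ang2_frac_tetramer",
             # baseline-equilibrium complex occupancies, not free abundances
             "R1R2_0", "NRP1R1_0", "TC_0", "TCR2_0", "T1T2_0",
             "sTie2_0", "sTie1_0", "VEGFR2i_0")
  v <- c(
    ## VEGF/VEGFR2 receptor layer
    konvegfr2 = 1, koffvegfr2 = 0.5,
    kdimvegfr2 = 10, kundimvegfr2 = 0.1,
    kphosvegfr2 = 5, kdephosvegfr2 = 0.5,
    konvegfr1 = 10, koffvegfr1 = 0.1,
    konr1r2 = 1, koffr1r2 = 0.1,
    konvegfnrp1 = 1, koffvegfnrp1 = 1,
    konnrp1r1 = 1, koffnrp1r1 = 0.1,
    kontsp1cd47 = 1, kofftsp1cd47 = 0.1,
    koncd47r2 = 1, koffcd47r2 = 0.1,
    kintvegfr2 = 0.04, krecvegfr2 = 0.08, kdegvegfr2 = 0.03,
    ksynvegfr2 = 1.082e-3,
    kintpvegfr2 = 0.3, kdegvegfr2dpe2_nrp = 0.1,
    VEGFR2_0 = 0.0991833, VEGFR2i_0 = 0.0360667, VEGFR1_0 = 0.0133083,
    R1R2_0 = 0.0132018, NRP1_0 = 0.17651, NRP1R1_0 = 0.0234903,
    TSP1_0 = 0.0118377, CD47_0 = 0.161837, TC_0 = 0.0191578,
    TCR2_0 = 0.0190045,
    ## Ang/Tie receptor layer
    konang1tie2 = 5, koffang1tie2 = 0.2,
    konang2tie2 = 5, koffang2tie2 = 0.1,
    kclusttie2 = 30, kdeclusttie2 = 0.01,
    ang2_agonist_factor = 0.05,
    kphostie2 = 5, kdephostie2 = 0.5,
    ktransloctie2 = 0.12,
    kcatveptp = 0.5, kmveptp = 0.05, tie1_shield_factor = 0.1,
    kdisassemblytie2 = 0.2,
    kontie1tie2 = 2, kofftie1tie2 = 0.2,
    kontie1junc = 5, kofftie1junc = 0.05,
    kshedtie2 = 0.002, kshedtie1 = 0.002,
    kshedvegf = 0.0022, kmshedvegf = 0.0015,
    ksyntie2 = 4e-4, ksyntie1 = 2e-4,
    kclearstie2 = 0.01, kclearstie1 = 0.01,
    konstie2ang1 = 5, koffstie2ang1 = 0.1,
    konstie2ang2 = 5, koffstie2ang2 = 0.5,
    kdegptie2 = 0.005,
    Tie2_0 = 0.2, Tie1_0 = 0.1, T1T2_0 = 0.2, VEPTP_0 = 0.1,
    sTie2_0 = 0.04, sTie1_0 = 0.02,
    ## crosstalk
    kcats1p = 0.5, kms1pact = 0.006, kdegs1p = 0.3, Sph_0 = 1,
    krelang2 = 0.025, WPB_Ang2_0 = 80, kclearang2 = 0.005,
    ## downstream
    kactivesrc = 20, kdephossrc = 0.5, Src_0 = 0.5,
    kactrhoa = 0.6, khydrolrhoa = 0.05, RhoA_0 = 1,
    konrhomdia = 5, koffrhomdia = 0.05, mDia_0 = 0.48,
    konmdiasrc = 10, koffmdiasrc = 0.03,
    kcatsrcvecad = 1.5, kdephosvecad = 0.4, VEcad_0 = 1,
    kactaxl = 5, kdephosaxl = 0.3, Axl_0 = 0.3,
    kactpi3ksrc = 0.25, kactpi3kaxl = 0.15, kactpi3ktie2 = 3, kactpi3kdag = 4,
    kinactPI3K = 6, PI3K_0 = 1,
    kcatPI3KAkt = 2, kmpi3kakt = 0.5, kdephosakt = 0.5, Akt_0 = 1,
    kcatenos = 2, kmcaenos = 150, kdephosenos = 0.3, eNOS_0 = 1,
    kactplcg = 10, kdephosplcg = 0.5, PLCgamma_0 = 1,
    kcatplcgip3 = 1, kdegip3 = 0.5,
    kcatPLCgammaDAG = 2, kdegdag = 0.5, kmdags1p = 0.12,
    kip3rel = 0.03, kleakca = 0.004, vserca = 30, kmserca = 300,
    CaER_0 = 1003.65, Cacyto_0 = 46.3484,
    kcatrafdag = 2, kms1praf = 0.1, kmcaraf = 150, kinactraf = 0.3,
    Raf_0 = 1,
    kcatrafmek = 2, kdephosmek = 0.4, MEK_0 = 1,
    kcatmekerk = 2, kdephoserk = 0.4, Erk_0 = 1,
    ## structural constants
    mw_vegf = 45, mw_ang1_tetramer = 280, mw_ang2_monomer = 66,
    ang2_frac_dimer = 0.4, ang2_frac_trimer = 0.3, ang2_frac_tetramer = 0.3
  )
  meta <- stats::setNames(rep("calibrated", length(v)), names(v))
  meta[fixed] <- "fixed"
  meta[grepl("_0$", names(v))] <- "literature"
  parameter_set(v, meta = meta)
}

#' Parameter keys varied in global sensitivity analysis
#'
#' All kinetic constants and initial abundances; structural constants
#' (molecular weights, Ang2 multimer mixture fractions) are excluded.
#'
#' @param params A [parameter_set()] (defaults to the packaged baseline).
#' @return Character vector of parameter keys.
#' @export
sensitivity_parameter_keys <- function(params = default_parameters()) {
  names(params$values)[params$meta != "fixed"]
}

.sp <- function(...) species_def(...)

#' Build the default endothelial signaling network
#'
#' Assembles the coarse-grained species state space and reaction rules of the
#' coupled VEGF/Ang-Tie network and returns a validated [network_model()].
#' Ligand-induced Tie2 clustering is lumped as a two-step process (ligand-Tie2
#' seed, then a cluster of four Tie2); only clusters autophosphorylate.
#' Ang2 dimers/trimers occupy Tie2 competitively without clustering; the Ang2
#' tetramer is a weak agonist.  See \code{vignette("endonet-methods")} for the
#' full mechanism table.
#'
#' @param config A [model_config()].
#' @param params A [parameter_set()] used to validate key references.
#' @return A \code{network_model}.
#' @export
build_default_model <- function(config = model_config(),
                                params = default_parameters()) {
  m <- config$modules
  has <- function(x) x %in% m
  sp <- list()
  rx <- list()
  obs <- list()

  if (has("vegf")) {
    sp <- c(sp, list(
      .sp("VEGF", "extracellular", c(VEGF = 1)),
      .sp("R2", "surface", c(VEGFR2 = 1), "VEGFR2_0"),
      .sp("VR2", "surface", c(VEGF = 1, VEGFR2 = 1)),
      .sp("R2dim", "surface", c(VEGF = 1, VEGFR2 = 2)),
      .sp("pR2dim", "surface", c(VEGF = 1, VEGFR2 = 2)),
      .sp("R1", "surface", c(VEGFR1 = 1), "VEGFR1_0"),
      .sp("VR1", "surface", c(VEGF = 1, VEGFR1 = 1)),
      .sp("R1R2", "surface", c(VEGFR1 = 1, VEGFR2 = 1), "R1R2_0"),
      .sp("NRP1", "surface", c(NRP1 = 1), "NRP1_0"),
      .sp("VN", "surface", c(VEGF = 1, NRP1 = 1)),
      .sp("NRP1R1", "surface", c(NRP1 = 1, VEGFR1 = 1), "NRP1R1_0"),
      .sp("TSP1", "extracellular", c(TSP1 = 1), "TSP1_0"),
      .sp("CD47", "surface", c(CD47 = 1), "CD47_0"),
      .sp("TC", "surface", c(TSP1 = 1, CD47 = 1), "TC_0"),
      .sp("TCR2", "surface", c(TSP1 = 1, CD47 = 1, VEGFR2 = 1), "TCR2_0"),
      .sp("R2i", "internalized", c(VEGFR2 = 1), "VEGFR2i_0"),
      .sp("pR2i", "internalized", c(VEGF = 1, VEGFR2 = 2))))
    obs$pVEGFR2 <- c(pR2dim = 1)
    obs$VEGFR2_surface <- c(R2 = 1, VR2 = 1, R2dim = 2, pR2dim = 2,
                            R1R2 = 1, TCR2 = 1)
    obs$VEGFR2_total <- c(R2 = 1, VR2 = 1, R2dim = 2, pR2dim = 2,
                          R1R2 = 1, TCR2 = 1, R2i = 1, pR2i = 2)
    rx <- c(rx, list(
      reaction_rule("vegf_r2_bind", c(VEGF = 1, R2 = 1), c(VR2 = 1),
                    k = "konvegfr2", rev = "koffvegfr2"),
      reaction_rule("r2_dimerize", c(VR2 = 1, R2 = 1), c(R2dim = 1),
                    k = "kdimvegfr2", rev = "kundimvegfr2"),
      reaction_rule("r2_autophos", c(R2dim = 1), c(pR2dim = 1),
                    k = "kphosvegfr2", tag = "VEGFR2"),
      reaction_rule("r2_dephos", c(pR2dim = 1), c(R2dim = 1),
                    k = "kdephosvegfr2"),
      reaction_rule("vegf_r1_bind", c(VEGF = 1, R1 = 1), c(VR1 = 1),
                    k = "konvegfr1", rev = "koffvegfr1"),
      reaction_rule("r1_r2_heterodim", c(R1 = 1, R2 = 1), c(R1R2 = 1),
                    k = "konr1r2", rev = "koffr1r2"),
      reaction_rule("vegf_nrp1_bind", c(VEGF = 1, NRP1 = 1), c(VN = 1),
                    k = "konvegfnrp1", rev = "koffvegfnrp1"),
      reaction_rule("nrp1_r1_bind", c(NRP1 = 1, R1 = 1), c(NRP1R1 = 1),
                    k = "konnrp1r1", rev = "koffnrp1r1"),
      reaction_rule("tsp1_cd47_bind", c(TSP1 = 1, CD47 = 1), c(TC = 1),
                    k = "kontsp1cd47", rev = "kofftsp1cd47"),
      reaction_rule("tc_r2_bind", c(TC = 1, R2 = 1), c(TCR2 = 1),
                    k = "koncd47r2", rev = "koffcd47r2"),
      reaction_rule("r2_internalize", c(R2 = 1), c(R2i = 1),
                    k = "kintvegfr2"),
      reaction_rule("r2_recycle", c(R2i = 1), c(R2 = 1), k = "krecvegfr2"),
      reaction_rule("r2_degrade", c(R2i = 1), NULL, k = "kdegvegfr2",
                    non_conserving = TRUE),
      reaction_rule("r2_synthesize", NULL, c(R2 = 1), k = "ksynvegfr2",
                    non_conserving = TRUE),
      reaction_rule("pr2_internalize", c(pR2dim = 1), c(pR2i = 1),
                    k = "kintpvegfr2"),
      reaction_rule("r2dim_internalize", c(R2dim = 1), c(pR2i = 1),
                    k = "kintpvegfr2"),
      reaction_rule("pr2i_degrade", c(pR2i = 1), NULL,
                    k = "kdegvegfr2dpe2_nrp", non_conserving = TRUE)))
  }

  if (has("tie")) {
    sp <- c(sp, list(
      .sp("Ang1", "extracellular", c(Ang1 = 1)),
      .sp("A2d", "extracellular", c(Ang2 = 2)),
      .sp("A2t", "extracellular", c(Ang2 = 3)),
      .sp("A2q", "extracellular", c(Ang2 = 4)),
      .sp("Tie2", "surface", c(Tie2 = 1), "Tie2_0"),
      .sp("Tie1", "surface", c(Tie1 = 1), "Tie1_0"),
      .sp("T1T2", "surface", c(Tie1 = 1, Tie2 = 1), "T1T2_0"),
      .sp("A1T", "surface", c(Ang1 = 1, Tie2 = 1)),
      .sp("A1c", "surface", c(Ang1 = 1, Tie2 = 4)),
      .sp("pA1c", "surface", c(Ang1 = 1, Tie2 = 4)),
      .sp("jpA1c", "junctional", c(Ang1 = 1, Tie2 = 4)),
      .sp("jA1c", "junctional", c(Ang1 = 1, Tie2 = 4)),
      .sp("jpA1T1", "junctional", c(Ang1 = 1, Tie2 = 4, Tie1 = 1)),
      .sp("A2dT", "surface", c(Ang2 = 2, Tie2 = 1)),
      .sp("A2tT", "surface", c(Ang2 = 3, Tie2 = 1)),
      .sp("A2qT", "surface", c(Ang2 = 4, Tie2 = 1)),
      .sp("A2c", "surface", c(Ang2 = 4, Tie2 = 4)),
      .sp("pA2c", "surface", c(Ang2 = 4, Tie2 = 4)),
      .sp("jpA2c", "junctional", c(Ang2 = 4, Tie2 = 4)),
      .sp("jA2c", "junctional", c(Ang2 = 4, Tie2 = 4)),
      .sp("jpA2T1", "junctional", c(Ang2 = 4, Tie2 = 4, Tie1 = 1)),
      .sp("sTie2", "extracellular", c(sTie2 = 1), "sTie2_0"),
      .sp("sTie1", "extracellular", c(sTie1 = 1), "sTie1_0"),
      .sp("sA1", "extracellular", c(sTie2 = 1, Ang1 = 1)),
      .sp("sA2d", "extracellular", c(sTie2 = 1, Ang2 = 2)),
      .sp("sA2t", "extracellular", c(sTie2 = 1, Ang2 = 3)),
      .sp("sA2q", "extracellular", c(sTie2 = 1, Ang2 = 4)),
      .sp("VEPTP", "junctional", c(VEPTP = 1), "VEPTP_0")))
    obs$pTie2_surface <- c(pA1c = 4, pA2c = 4)
    obs$pTie2_junctional <- c(jpA1c = 4, jpA2c = 4, jpA1T1 = 4, jpA2T1 = 4)
    obs$pTie2 <- c(pA1c = 4, pA2c = 4, jpA1c = 4, jpA2c = 4,
                   jpA1T1 = 4, jpA2T1 = 4)
    obs$sTie2 <- c(sTie2 = 1, sA1 = 1, sA2d = 1, sA2t = 1, sA2q = 1)
    obs$Ang2_extracellular <- c(A2d = 2, A2t = 3, A2q = 4)
    clusterchain <- function(pre, seed, cl, pcl, jp, j, jT1, agonist_scale) {
      list(
        reaction_rule(paste0(pre, "_cluster"),
                      stats::setNames(c(1L, 3L), c(seed, "Tie2")),
                      stats::setNames(1L, cl),
                      k = if (is.null(agonist_scale)) "kclusttie2"
                          else c("kclusttie2", agonist_scale),
                      rev = "kdeclusttie2"),
        reaction_rule(paste0(pre, "_phos"), stats::setNames(1L, cl),
                      stats::setNames(1L, pcl), k = "kphostie2"),
        reaction_rule(paste0(pre, "_surf_dephos"), stats::setNames(1L, pcl),
                      stats::setNames(1L, cl), k = "kdephostie2"),
        reaction_rule(paste0(pre, "_transloc"), stats::setNames(1L, pcl),
                      stats::setNames(1L, jp), k = "ktransloctie2"),
        reaction_rule(paste0(pre, "_veptp"), stats::setNames(1L, jp),
                      stats::setNames(1L, j), law = "michaelis_menten",
                      k = "kcatveptp", Km = "kmveptp", modifier = "VEPTP"),
        reaction_rule(paste0(pre, "_tie1_stabilize"),
                      stats::setNames(c(1L, 1L), c(jp, "Tie1")),
                      stats::setNames(1L, jT1),
                      k = "kontie1junc", rev = "kofftie1junc"),
        reaction_rule(paste0(pre, "_veptp_shielded"),
                      stats::setNames(1L, jT1),
                      stats::setNames(c(1L, 1L), c(j, "Tie1")),
                      law = "michaelis_menten", k = c("kcatveptp",
                                                      "tie1_shield_factor"),
                      Km = "kmveptp", modifier = "VEPTP"),
        reaction_rule(paste0(pre, "_ptie2_degrade"), stats::setNames(1L, jp),
                      NULL, k = "kdegptie2", non_conserving = TRUE))
    }
    rx <- c(rx, list(
      reaction_rule("ang1_tie2_bind", c(Ang1 = 1, Tie2 = 1), c(A1T = 1),
                    k = "konang1tie2", rev = "koffang1tie2"),
      reaction_rule("ang2d_tie2_bind", c(A2d = 1, Tie2 = 1), c(A2dT = 1),
                    k = "konang2tie2", rev = "koffang2tie2"),
      reaction_rule("ang2t_tie2_bind", c(A2t = 1, Tie2 = 1), c(A2tT = 1),
                    k = "konang2tie2", rev = "koffang2tie2"),
      reaction_rule("ang2q_tie2_bind", c(A2q = 1, Tie2 = 1), c(A2qT = 1),
                    k = "konang2tie2", rev = "koffang2tie2"),
      reaction_rule("tie1_tie2_heterodim", c(Tie1 = 1, Tie2 = 1),
                    c(T1T2 = 1), k = "kontie1tie2", rev = "kofftie1tie2"),
      reaction_rule("a1_disassemble", c(jA1c = 1), c(Ang1 = 1, Tie2 = 4),
                    k = "kdisassemblytie2"),
      reaction_rule("a2_disassemble", c(jA2c = 1), c(A2q = 1, Tie2 = 4),
                    k = "kdisassemblytie2"),
      reaction_rule("tie2_shed_const", c(Tie2 = 1), c(sTie2 = 1),
                    k = "kshedtie2", non_conserving = TRUE),
      reaction_rule("tie1_shed_const", c(Tie1 = 1), c(sTie1 = 1),
                    k = "kshedtie1", non_conserving = TRUE),
      reaction_rule("tie2_synthesize", NULL, c(Tie2 = 1), k = "ksyntie2",
                    non_conserving = TRUE),
      reaction_rule("tie1_synthesize", NULL, c(Tie1 = 1), k = "ksyntie1",
                    non_conserving = TRUE),
      reaction_rule("stie2_clear", c(sTie2 = 1), NULL, k = "kclearstie2",
                    non_conserving = TRUE),
      reaction_rule("stie1_clear", c(sTie1 = 1), NULL, k = "kclearstie1",
                    non_conserving = TRUE),
      reaction_rule("stie2_trap_ang1", c(sTie2 = 1, Ang1 = 1), c(sA1 = 1),
                    k = "konstie2ang1", rev = "koffstie2ang1"),
      reaction_rule("stie2_trap_ang2d", c(sTie2 = 1, A2d = 1), c(sA2d = 1),
                    k = "konstie2ang2", rev = "koffstie2ang2"),
      reaction_rule("stie2_trap_ang2t", c(sTie2 = 1, A2t = 1), c(sA2t = 1),
                    k = "konstie2ang2", rev = "koffstie2ang2"),
      reaction_rule("stie2_trap_ang2q", c(sTie2 = 1, A2q = 1), c(sA2q = 1),
                    k = "konstie2ang2", rev = "koffstie2ang2")),
      clusterchain("a1", "A1T", "A1c", "pA1c", "jpA1c", "jA1c", "jpA1T1",
                   NULL),
      clusterchain("a2", "A2qT", "A2c", "pA2c", "jpA2c", "jA2c", "jpA2T1",
                   "ang2_agonist_factor"))
  }

  if (has("downstream")) {
    sp <- c(sp, list(
      .sp("Src", "cytosol", c(Src = 1), "Src_0"),
      .sp("pSrc", "cytosol", c(Src = 1)),
      .sp("VEcad", "junctional", c(VEcad = 1), "VEcad_0"),
      .sp("pVEcad", "junctional", c(VEcad = 1)),
      .sp("Axl", "surface", c(Axl = 1), "Axl_0"),
      .sp("pAxl", "surface", c(Axl = 1)),
      .sp("PI3K", "cytosol", c(PI3K = 1), "PI3K_0"),
      .sp("PI3Ka", "cytosol", c(PI3K = 1)),
      .sp("Akt", "cytosol", c(Akt = 1), "Akt_0"),
      .sp("ppAkt", "cytosol", c(Akt = 1)),
      .sp("eNOS", "cytosol", c(eNOS = 1), "eNOS_0"),
      .sp("peNOS", "cytosol", c(eNOS = 1)),
      .sp("PLCg", "cytosol", c(PLCg = 1), "PLCgamma_0"),
      .sp("pPLCg", "cytosol", c(PLCg = 1)),
      .sp("IP3", "cytosol", c(IP3 = 1)),
      .sp("DAG", "cytosol", c(DAG = 1)),
      .sp("CaER", "ER", c(Ca = 1), "CaER_0"),
      .sp("Cacyto", "cytosol", c(Ca = 1), "Cacyto_0"),
      .sp("Sph", "cytosol", c(Sph = 1), "Sph_0"),
      .sp("S1P", "cytosol", c(Sph = 1)),
      .sp("Raf", "cytosol", c(Raf = 1), "Raf_0"),
      .sp("aRaf", "cytosol", c(Raf = 1)),
      .sp("MEK", "cytosol", c(MEK = 1), "MEK_0"),
      .sp("pMEK", "cytosol", c(MEK = 1)),
      .sp("Erk", "cytosol", c(Erk = 1), "Erk_0"),
      .sp("pErk", "cytosol", c(Erk = 1))))
    obs$pSrc <- c(pSrc = 1)
    obs$freeSrc <- c(Src = 1)
    obs$pVEcad <- c(pVEcad = 1)
    obs$pAxl <- c(pAxl = 1)
    obs$ppAkt <- c(ppAkt = 1)
    obs$peNOS <- c(peNOS = 1)
    obs$pPLCg <- c(pPLCg = 1)
    obs$Ca_cyto <- c(Cacyto = 1)
    obs$S1P <- c(S1P = 1)
    obs$pErk <- c(pErk = 1)
    # dephosphorylation / deactivation, receptor-independent
    rx <- c(rx, list(
      reaction_rule("src_dephos", c(pSrc = 1), c(Src = 1), k = "kdephossrc"),
      reaction_rule("vecad_phos", c(VEcad = 1), c(pVEcad = 1),
                    k = "kcatsrcvecad", modifier = "pSrc", tag = "Src"),
      reaction_rule("vecad_dephos", c(pVEcad = 1), c(VEcad = 1),
                    k = "kdephosvecad"),
      reaction_rule("axl_dephos", c(pAxl = 1), c(Axl = 1), k = "kdephosaxl"),
      reaction_rule("pi3k_act_axl", c(PI3K = 1), c(PI3Ka = 1),
                    k = "kactpi3kaxl", modifier = "pAxl", tag = "Axl"),
      reaction_rule("pi3k_inact", c(PI3Ka = 1), c(PI3K = 1),
                    k = "kinactPI3K"),
      reaction_rule("pi3k_act_dag", c(PI3K = 1), c(PI3Ka = 1),
                    k = "kactpi3kdag", modifier = "DAG"),
      reaction_rule("akt_act", c(Akt = 1), c(ppAkt = 1),
                    law = "michaelis_menten", k = "kcatPI3KAkt",
                    Km = "kmpi3kakt", modifier = "PI3Ka", tag = "Akt"),
      reaction_rule("akt_dephos", c(ppAkt = 1), c(Akt = 1),
                    k = "kdephosakt"),
      reaction_rule("enos_act", c(eNOS = 1), c(peNOS = 1), k = "kcatenos",
                    modifier = "ppAkt",
                    sat = list(c("Cacyto", "kmcaenos")), tag = "Akt"),
      reaction_rule("enos_dephos", c(peNOS = 1), c(eNOS = 1),
                    k = "kdephosenos"),
      reaction_rule("plcg_dephos", c(pPLCg = 1), c(PLCg = 1),
                    k = "kdephosplcg"),
      reaction_rule("ip3_synth", NULL, c(IP3 = 1), k = "kcatplcgip3",
                    modifier = "pPLCg", non_conserving = TRUE),
      reaction_rule("ip3_degrade", c(IP3 = 1), NULL, k = "kdegip3",
                    non_conserving = TRUE),
      reaction_rule("dag_synth", NULL, c(DAG = 1), k = "kcatPLCgammaDAG",
                    modifier = "pPLCg", non_conserving = TRUE),
      reaction_rule("dag_degrade", c(DAG = 1), NULL, k = "kdegdag",
                    non_conserving = TRUE),
      reaction_rule("ca_ip3_release", c(CaER = 1), c(Cacyto = 1),
                    k = "kip3rel", modifier = "IP3"),
      reaction_rule("ca_leak", c(CaER = 1), c(Cacyto = 1), k = "kleakca"),
      reaction_rule("ca_serca", c(Cacyto = 1), c(CaER = 1),
                    law = "saturating_hill", k = "vserca", Km = "kmserca"),
      reaction_rule("s1p_deact", c(S1P = 1), c(Sph = 1), k = "kdegs1p"),
      reaction_rule("raf_act", c(Raf = 1), c(aRaf = 1),
                    k = "kcatrafdag", modifier = "DAG",
                    sat = list(c("S1P", "kms1praf"), c("Cacyto", "kmcaraf"))),
      reaction_rule("raf_inact", c(aRaf = 1), c(Raf = 1), k = "kinactraf"),
      reaction_rule("mek_act", c(MEK = 1), c(pMEK = 1), k = "kcatrafmek",
                    modifier = "aRaf"),
      reaction_rule("mek_dephos", c(pMEK = 1), c(MEK = 1), k = "kdephosmek"),
      reaction_rule("erk_act", c(Erk = 1), c(pErk = 1), k = "kcatmekerk",
                    modifier = "pMEK"),
      reaction_rule("erk_dephos", c(pErk = 1), c(Erk = 1), k = "kdephoserk")))
    if (has("vegf")) {
      rx <- c(rx, list(
        reaction_rule("src_act", c(Src = 1), c(pSrc = 1), k = "kactivesrc",
                      modifier = "pVEGFR2", tag = "Src"),
        reaction_rule("axl_transact", c(Axl = 1), c(pAxl = 1), k = "kactaxl",
                      modifier = "pVEGFR2"),
        reaction_rule("pi3k_act_src", c(PI3K = 1), c(PI3Ka = 1),
                      k = "kactpi3ksrc", modifier = "pSrc", tag = "Src"),
        reaction_rule("plcg_act", c(PLCg = 1), c(pPLCg = 1), k = "kactplcg",
                      modifier = "pVEGFR2", tag = "VEGFR2"),
        reaction_rule("s1p_act", c(Sph = 1), c(S1P = 1), k = "kcats1p",
                      sat = list(c("pVEGFR2", "kms1pact"),
                                 c("DAG", "kmdags1p")))))
    }
    if (has("tie")) {
      sp <- c(sp, list(
        .sp("RhoAGDP", "cytosol", c(RhoA = 1), "RhoA_0"),
        .sp("RhoAGTP", "cytosol", c(RhoA = 1)),
        .sp("mDia", "cytosol", c(mDia = 1), "mDia_0"),
        .sp("RmD", "cytosol", c(RhoA = 1, mDia = 1)),
        .sp("RmDSrc", "cytosol", c(RhoA = 1, mDia = 1, Src = 1))))
      obs$RhoA_GTP <- c(RhoAGTP = 1, RmD = 1, RmDSrc = 1)
      obs$mDiaSrc_complex <- c(RmDSrc = 1)
      obs$totalSrc <- c(Src = 1, pSrc = 1, RmDSrc = 1)
      rx <- c(rx, list(
        reaction_rule("rhoa_act", c(RhoAGDP = 1), c(RhoAGTP = 1),
                      k = "kactrhoa", modifier = "pTie2_junctional"),
        reaction_rule("rhoa_hydrolyze", c(RhoAGTP = 1), c(RhoAGDP = 1),
                      k = "khydrolrhoa"),
        reaction_rule("rhoa_mdia_bind", c(RhoAGTP = 1, mDia = 1),
                      c(RmD = 1), k = "konrhomdia", rev = "koffrhomdia"),
        reaction_rule("mdia_src_sequester", c(RmD = 1, Src = 1),
                      c(RmDSrc = 1), k = "konmdiasrc", rev = "koffmdiasrc"),
        reaction_rule("pi3k_act_tie2", c(PI3K = 1), c(PI3Ka = 1),
                      k = "kactpi3ktie2", modifier = "pTie2_junctional")))
    } else {
      obs$totalSrc <- c(Src = 1, pSrc = 1)
    }
  }

  if (has("crosstalk")) {
    sp <- c(sp, list(
      .sp("WPB", "WPB", c(Ang2 = 1), "WPB_Ang2_0"),
      .sp("Ang2cum", "extracellular", NULL)))
    obs$Ang2_released <- c(Ang2cum = 1)
    rx <- c(rx, list(
      reaction_rule("tie2_shed_vegf", c(Tie2 = 1), c(sTie2 = 1),
                    k = "kshedvegf", sat = list(c("pVEGFR2", "kmshedvegf")),
                    non_conserving = TRUE),
      reaction_rule("wpb_release_dim", c(WPB = 2), c(A2d = 1, Ang2cum = 2),
                    k = c("krelang2", "ang2_frac_dimer"), modifier = "S1P"),
      reaction_rule("wpb_release_tri", c(WPB = 3), c(A2t = 1, Ang2cum = 3),
                    k = c("krelang2", "ang2_frac_trimer"), modifier = "S1P"),
      reaction_rule("wpb_release_tet", c(WPB = 4), c(A2q = 1, Ang2cum = 4),
                    k = c("krelang2", "ang2_frac_tetramer"),
                    modifier = "S1P"),
      reaction_rule("ang2d_clear", c(A2d = 1), NULL, k = "kclearang2",
                    non_conserving = TRUE),
      reaction_rule("ang2t_clear", c(A2t = 1), NULL, k = "kclearang2",
                    non_conserving = TRUE),
      reaction_rule("ang2q_clear", c(A2q = 1), NULL, k = "kclearang2",
                    non_conserving = TRUE)))
  }

  network_model(sp, rx, obs, params, config)
}
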