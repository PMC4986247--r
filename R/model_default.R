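# Default ATM/p53/NF-kB/Wip1 network.
#
# Levels are molecule counts per cell; time is in seconds.  Degradation rates
# are derived from declared half-lives (rate = ln 2 / t_half); synthesis
# constants balance the declared resting levels; coupling strengths marked
# fitted = TRUE were calibrated by trial and error against benchmark U2-OS
# observations (Wip1 transcript peak ~2 h and protein peak ~18 h after 10 Gy,
# ~4-fold Wip1 reduction under shRNA knockdown, clonogenic dose response).

hl <- function(t_half_s) log(2) / t_half_s

#' Build the default DNA-damage-response model
#'
#' Assembles the full ATM/p53/NF-kB/Wip1 network: DSB detection by ATM with
#' the MRN complex, Chk2, the p53-Mdm2 core (cytoplasmic, nuclear and
#' multi-phosphorylated inactive nuclear Mdm2, with Mdm2/MdmX merged), Wip1
#' with its transcript regulators miR-16/KSRP/CREB, the TNF-responsive
#' IKK/IkB/A20/NF-kB module, and the fate readouts p21 and Bax.  Genes for
#' Wip1, Chk2 and ATM switch stochastically; DSBs and TNF receptors are
#' discrete counters.
#'
#' @return a validated `ddr_model`.
#' @export
build_default_model <- function() {
  # --- half-lives (s) ---------------------------------------------------
  t_mrn  <- 36000; t_atm <- 36000; t_chk2 <- 28800
  t_p53  <- 12600; t_mdm2 <- 1800
  t_wm   <- 5400;  t_w   <- 64800
  t_mir  <- 28800; t_ksrp <- 28800; t_creb <- 28800
  t_nfkb <- 36000; t_ikb <- 1800; t_ikk <- 18000; t_a20 <- 3600
  t_p21m <- 3600;  t_p21 <- 10800; t_baxm <- 14400; t_bax <- 64800

  species <- rbind(
    ddr_species("MRN",       "nucleus",   "complex",            init = 3000),
    ddr_species("ATM",       "nucleus",   "protein",            init = 9000),
    ddr_species("ATMa",      "nucleus",   "protein_phospho",    init = 250),
    ddr_species("CHK2",      "nucleus",   "protein",            init = 5000),
    ddr_species("CHK2a",     "nucleus",   "protein_phospho",    init = 100),
    ddr_species("P53_cyt",   "cytoplasm", "protein",            init = 2000),
    ddr_species("P53_nuc",   "nucleus",   "protein",            init = 450),
    ddr_species("P53a_nuc",  "nucleus",   "protein_phospho",    init = 100),
    ddr_species("MDM2_cyt",  "cytoplasm", "protein",            init = 1500),
    ddr_species("MDM2_nuc",  "nucleus",   "protein",            init = 390),
    ddr_species("MDM2pp_nuc","nucleus",   "protein_multiphospho", init = 10),
    ddr_species("WIP1_mRNA", "cytoplasm", "mRNA",               init = 2),
    ddr_species("WIP1",      "nucleus",   "protein",            init = 150),
    ddr_species("MIR16",     "nucleus",   "miRNA",              init = 400),
    ddr_species("KSRP",      "cytoplasm", "protein",            init = 2000),
    ddr_species("KSRPa",     "cytoplasm", "protein_phospho",    init = 30),
    ddr_species("CREB",      "nucleus",   "protein",            init = 3000),
    ddr_species("CREBa",     "nucleus",   "protein_phospho",    init = 50),
    ddr_species("NFKB_cyt",  "cytoplasm", "protein",            init = 10000),
    ddr_species("NFKB_nuc",  "nucleus",   "protein",            init = 100),
    ddr_species("IKB",       "cytoplasm", "protein",            init = 2000),
    ddr_species("IKKn",      "cytoplasm", "protein",            init = 2000),
    ddr_species("IKKa",      "cytoplasm", "protein_phospho",    init = 5),
    ddr_species("A20",       "cytoplasm", "protein",            init = 500),
    ddr_species("P21_mRNA",  "cytoplasm", "mRNA",               init = 40),
    ddr_species("P21",       "nucleus",   "protein",            init = 400),
    ddr_species("BAX_mRNA",  "cytoplasm", "mRNA",               init = 20),
    ddr_species("BAX",       "cytoplasm", "protein",            init = 200),
    ddr_species("DSB",       "nucleus",   "complex",  "stochastic", init = 0),
    ddr_species("TNFR",  "extracellular", "protein",  "stochastic", init = 0))

  p <- function(name, value, fitted = FALSE, half_life = NA_real_,
                desc = "") {
    data.frame(name = name, value = value, fitted = fitted,
               half_life = half_life, desc = desc, stringsAsFactors = FALSE)
  }
  params <- rbind(
    # degradation rates (from half-lives)
    p("d_mrn",  hl(t_mrn),  half_life = t_mrn),
    p("d_atm",  hl(t_atm),  half_life = t_atm),
    p("d_chk2", hl(t_chk2), half_life = t_chk2),
    p("d_p53",  hl(t_p53),  half_life = t_p53),
    p("d_mdm2", hl(t_mdm2), half_life = t_mdm2),
    p("d_wip1m", hl(t_wm),  half_life = t_wm),
    p("d_wip1", hl(t_w),    half_life = t_w),
    p("d_mir16", hl(t_mir), half_life = t_mir),
    p("d_ksrp", hl(t_ksrp), half_life = t_ksrp),
    p("d_creb", hl(t_creb), half_life = t_creb),
    p("d_nfkb", hl(t_nfkb), half_life = t_nfkb),
    p("d_ikb",  hl(t_ikb),  half_life = t_ikb),
    p("d_ikk",  hl(t_ikk),  half_life = t_ikk),
    p("d_a20",  hl(t_a20),  half_life = t_a20),
    p("d_p21m", hl(t_p21m), half_life = t_p21m),
    p("d_p21",  hl(t_p21),  half_life = t_p21),
    p("d_baxm", hl(t_baxm), half_life = t_baxm),
    p("d_bax",  hl(t_bax),  half_life = t_bax),
    # synthesis (balances resting levels)
    p("s_mrn",  hl(t_mrn) * 3000),
    p("s_atm",  hl(t_atm) * 9250 / 2, desc = "per allele"),
    p("s_chk2", hl(t_chk2) * 5100 / 2, desc = "per allele"),
    p("s_p53_0", 1.4),
    p("s_p53_nf", 5e-3, fitted = TRUE,
      desc = "NF-kB-dependent p53 synthesis"),
    p("s_md0", 0.70),
    p("s_md_p53", 2e-3, desc = "p53-induced Mdm2 synthesis"),
    p("s_w0", 8e-4, desc = "basal Wip1 transcription per allele"),
    p("s_wp53", 5e-7, fitted = TRUE,
      desc = "p53-dependent Wip1 transcription"),
    p("s_wcreb", 1.6e-5, fitted = TRUE,
      desc = "CREB-dependent Wip1 transcription"),
    p("s_wnf", 4e-5, fitted = TRUE,
      desc = "NF-kB-dependent Wip1 transcription"),
    p("k_wtr", 7.5e-4, desc = "Wip1 translation per transcript"),
    p("s_mir0", 0.015),
    p("s_mir_ksrp", 2e-4, fitted = TRUE,
      desc = "KSRP-driven miR-16 biogenesis"),
    p("s_ksrp", hl(t_ksrp) * 2030),
    p("s_creb", hl(t_creb) * 3050),
    p("s_nfkb", hl(t_nfkb) * 10100),
    p("s_ikb0", 0.58),
    p("s_ikb_nf", 1.9e-3),
    p("s_ikk", hl(t_ikk) * 2005),
    p("s_a20_0", 0.077),
    p("s_a20_nf", 1.9e-4),
    p("s_p21m0", 5e-3),
    p("s_p21m", 4e-5, desc = "p53-dependent p21 transcription"),
    p("k_p21_tr", 6.4e-4),
    p("s_baxm0", 7e-4),
    p("s_baxm", 6.3e-3, desc = "p53-dependent Bax transcription (cooperative)"),
    p("K_baxm", 700, fitted = TRUE, desc = "p53 half-activation of Bax"),
    p("n_baxm", 3, desc = "Bax induction cooperativity"),
    p("k_bax_tr", 1.07e-4),
    # ATM module
    p("k_atm_act", 1.6e-3, fitted = TRUE,
      desc = "DSB/MRN-driven ATM autophosphorylation"),
    p("K_dsb_act", 250, fitted = TRUE, desc = "DSB count at half-max"),
    p("K_mrn", 1000),
    p("k_atma_deact", 5e-6, desc = "basal ATMa dephosphorylation"),
    p("k_wip_atm", 1.3e-3, fitted = TRUE,
      desc = "Wip1-catalysed ATMa dephosphorylation"),
    p("Km_wip_atm", 2000),
    # Chk2
    p("k_chk2_act", 1.8e-7),
    p("Km_chk2", 3000),
    p("k_chk2a_deact", 5e-5),
    p("k_wip_chk2", 2e-4, fitted = TRUE),
    p("Km_wip_chk2", 2000),
    # p53
    p("k_p53_imp", 3e-4, desc = "p53 nuclear import"),
    p("k_mdm_p53cyt", 2.57e-7, desc = "Mdm2-mediated p53 degradation (cyt)"),
    p("k_mdm_p53nuc", 2e-7, desc = "Mdm2-mediated p53 degradation (nuc)"),
    p("k_mdm_p53a", 3e-7),
    p("k_p53_act", 2e-4, desc = "ATMa-catalysed p53 phosphorylation"),
    p("k_p53_act_chk2", 1e-4),
    p("Km_p53act", 1000),
    p("k_p53a_deact", 5e-6),
    p("k_wip_p53", 9, fitted = TRUE,
      desc = "Wip1-catalysed p53 dephosphorylation (cooperative)"),
    p("K_wip_p53h", 270, fitted = TRUE,
      desc = "Wip1 half-saturation of p53a dephosphorylation"),
    p("n_wip_p53h", 3, desc = "Wip1 cooperativity on p53a"),
    p("Km_wip_p53", 2000),
    # Mdm2
    p("k_md_imp", 1e-4, desc = "Mdm2 nuclear import"),
    p("k_atm_mdm", 5e-8, desc = "ATMa-enhanced Mdm2 degradation"),
    p("k_mdm_pp", 3e-8, desc = "ATMa-driven Mdm2 multi-phosphorylation"),
    p("Km_mdm_pp", 1000),
    p("k_wip_mdm", 5e-5, fitted = TRUE,
      desc = "Wip1 reactivation of multi-phospho Mdm2"),
    p("Km_wip_mdm", 1000),
    # miR-16 action
    p("k_mir_deg", 2.4e-7, fitted = TRUE,
      desc = "miR-16-mediated Wip1 transcript degradation"),
    # KSRP / CREB activation
    p("k_ksrp_act", 2.8e-4),
    p("Km_ksrp", 2000),
    p("k_ksrpa_deact", 5e-4),
    p("k_creb_act", 2.8e-4),
    p("Km_creb", 2000),
    p("k_creba_deact", 1e-3),
    # NF-kB module
    p("k_nf_imp", 3e-4),
    p("K_nf_ikb", 30),
    p("k_nf_exp", 1e-6),
    p("k_ikb_deg", 5e-6, desc = "IKKa-driven IkB degradation"),
    p("k_ikk_act_r", 2.7e-5, desc = "receptor-driven IKK activation"),
    p("k_ikk_act_atm", 1.5e-8, fitted = TRUE,
      desc = "ATMa-driven IKK activation"),
    p("K_a20", 500),
    p("k_ikk_inact", 2e-3),
    # gene switching
    p("q0_wip1", 5e-6, fitted = TRUE),
    p("q_p53_wip1", 2e-9, fitted = TRUE,
      desc = "p53-proportional Wip1 gene activation"),
    p("q_creb_wip1", 2e-9, fitted = TRUE),
    p("q_nf_wip1", 1.5e-7, fitted = TRUE),
    p("K_wip_self", 60, fitted = TRUE,
      desc = "Wip1 self-inhibition of NF-kB-dependent activation"),
    p("d_g_wip1", 1.4e-6),
    p("q0_chk2", 6e-5),
    p("q_p53_chk2", 1e-7),
    p("K_chk2_p53", 3000, desc = "p53 inhibition of Chk2 gene activation"),
    p("d_g_chk2", 3e-5),
    p("q0_atm", 1.2e-4),
    p("q_creb_atm", 6e-8),
    p("d_g_atm", 3e-5),
    # DSB channel
    p("dsb_k_per_gy", 35, fitted = TRUE, desc = "DSB induced per Gy"),
    p("dsb_background", 3e-6, fitted = TRUE,
      desc = "spontaneous DSB appearance"),
    p("dsb_vmax", 1.5e-3, fitted = TRUE,
      desc = "repair-capacity-limited DSB repair"),
    p("dsb_km", 25, fitted = TRUE),
    # TNF receptor channel
    p("n_tnfr", 300),
    p("k_rec_act", 3e-4, desc = "per ng/ml per inactive receptor"),
    p("k_rec_deact", 1e-3))

  rx <- ddr_reaction
  reactions <- rbind(
    # MRN
    rx("mrn_syn", "s_mrn", dst = "MRN"),
    rx("mrn_deg", "d_mrn", src = "MRN", f1 = "lin:MRN"),
    # ATM (gene-controlled synthesis; activation needs DSBs + MRN)
    rx("atm_syn", "s_atm", dst = "ATM", f1 = "gene:g_atm"),
    rx("atm_deg", "d_atm", src = "ATM", f1 = "lin:ATM"),
    rx("atma_deg", "d_atm", src = "ATMa", f1 = "lin:ATMa"),
    rx("atm_act", "k_atm_act", src = "ATM", dst = "ATMa",
       f1 = "lin:ATM", f2 = "dsbmm:K_dsb_act", f3 = "mm:MRN:K_mrn"),
    rx("atma_deact", "k_atma_deact", src = "ATMa", dst = "ATM",
       f1 = "lin:ATMa"),
    rx("atma_deact_wip", "k_wip_atm", src = "ATMa", dst = "ATM",
       f1 = "lin:WIP1", f2 = "mm:ATMa:Km_wip_atm"),
    # Chk2
    rx("chk2_syn", "s_chk2", dst = "CHK2", f1 = "gene:g_chk2"),
    rx("chk2_deg", "d_chk2", src = "CHK2", f1 = "lin:CHK2"),
    rx("chk2a_deg", "d_chk2", src = "CHK2a", f1 = "lin:CHK2a"),
    rx("chk2_act", "k_chk2_act", src = "CHK2", dst = "CHK2a",
       f1 = "lin:ATMa", f2 = "lin:CHK2"),
    rx("chk2a_deact", "k_chk2a_deact", src = "CHK2a", dst = "CHK2",
       f1 = "lin:CHK2a"),
    rx("chk2a_deact_wip", "k_wip_chk2", src = "CHK2a", dst = "CHK2",
       f1 = "lin:WIP1", f2 = "mm:CHK2a:Km_wip_chk2"),
    # p53 cytoplasmic
    rx("p53c_syn", "s_p53_0", dst = "P53_cyt"),
    rx("p53c_syn_nf", "s_p53_nf", dst = "P53_cyt", f1 = "lin:NFKB_nuc"),
    rx("p53c_deg", "d_p53", src = "P53_cyt", f1 = "lin:P53_cyt"),
    rx("p53c_deg_mdm", "k_mdm_p53cyt", src = "P53_cyt",
       f1 = "lin:MDM2_cyt", f2 = "lin:P53_cyt"),
    rx("p53_import", "k_p53_imp", src = "P53_cyt", dst = "P53_nuc",
       f1 = "lin:P53_cyt", transport = TRUE),
    # p53 nuclear
    rx("p53n_deg", "d_p53", src = "P53_nuc", f1 = "lin:P53_nuc"),
    rx("p53n_deg_mdm", "k_mdm_p53nuc", src = "P53_nuc",
       f1 = "lin:MDM2_nuc", f2 = "lin:P53_nuc"),
    rx("p53_act_atm", "k_p53_act", src = "P53_nuc", dst = "P53a_nuc",
       f1 = "lin:ATMa", f2 = "mm:P53_nuc:Km_p53act"),
    rx("p53_act_chk2", "k_p53_act_chk2", src = "P53_nuc", dst = "P53a_nuc",
       f1 = "lin:CHK2a", f2 = "mm:P53_nuc:Km_p53act"),
    rx("p53a_deact", "k_p53a_deact", src = "P53a_nuc", dst = "P53_nuc",
       f1 = "lin:P53a_nuc"),
    rx("p53a_deact_wip", "k_wip_p53", src = "P53a_nuc", dst = "P53_nuc",
       f1 = "hill:WIP1:K_wip_p53h:n_wip_p53h",
       f2 = "mm:P53a_nuc:Km_wip_p53"),
    rx("p53a_deg", "d_p53", src = "P53a_nuc", f1 = "lin:P53a_nuc"),
    rx("p53a_deg_mdm", "k_mdm_p53a", src = "P53a_nuc",
       f1 = "lin:MDM2_nuc", f2 = "lin:P53a_nuc"),
    # Mdm2
    rx("mdm2c_syn", "s_md0", dst = "MDM2_cyt"),
    rx("mdm2c_syn_p53", "s_md_p53", dst = "MDM2_cyt", f1 = "lin:P53a_nuc"),
    rx("mdm2c_deg", "d_mdm2", src = "MDM2_cyt", f1 = "lin:MDM2_cyt"),
    rx("mdm2_import", "k_md_imp", src = "MDM2_cyt", dst = "MDM2_nuc",
       f1 = "lin:MDM2_cyt", transport = TRUE),
    rx("mdm2n_deg", "d_mdm2", src = "MDM2_nuc", f1 = "lin:MDM2_nuc"),
    rx("mdm2n_deg_atm", "k_atm_mdm", src = "MDM2_nuc",
       f1 = "lin:ATMa", f2 = "lin:MDM2_nuc"),
    rx("mdm2_pp", "k_mdm_pp", src = "MDM2_nuc", dst = "MDM2pp_nuc",
       f1 = "lin:ATMa", f2 = "lin:MDM2_nuc"),
    rx("mdm2_pp_back", "k_wip_mdm", src = "MDM2pp_nuc", dst = "MDM2_nuc",
       f1 = "lin:WIP1", f2 = "mm:MDM2pp_nuc:Km_wip_mdm"),
    rx("mdm2pp_deg", "d_mdm2", src = "MDM2pp_nuc", f1 = "lin:MDM2pp_nuc"),
    # Wip1 transcript (gene-scaled transcription; p53/CREB/NF-kB inputs,
    # the NF-kB input self-limited by Wip1)
    rx("wip1m_syn_0", "s_w0", dst = "WIP1_mRNA", f1 = "gene:g_wip1"),
    rx("wip1m_syn_p53", "s_wp53", dst = "WIP1_mRNA",
       f1 = "gene:g_wip1", f2 = "lin:P53a_nuc"),
    rx("wip1m_syn_creb", "s_wcreb", dst = "WIP1_mRNA",
       f1 = "gene:g_wip1", f2 = "lin:CREBa"),
    rx("wip1m_syn_nf", "s_wnf", dst = "WIP1_mRNA",
       f1 = "gene:g_wip1", f2 = "lin:NFKB_nuc", f3 = "inh:WIP1:K_wip_self"),
    rx("wip1m_deg", "d_wip1m", src = "WIP1_mRNA", f1 = "lin:WIP1_mRNA"),
    rx("wip1m_deg_mir", "k_mir_deg", src = "WIP1_mRNA",
       f1 = "lin:MIR16", f2 = "lin:WIP1_mRNA"),
    # Wip1 protein
    rx("wip1_syn", "k_wtr", dst = "WIP1", f1 = "lin:WIP1_mRNA"),
    rx("wip1_deg", "d_wip1", src = "WIP1", f1 = "lin:WIP1"),
    # miR-16 via KSRP
    rx("mir_syn_0", "s_mir0", dst = "MIR16"),
    rx("mir_syn_ksrp", "s_mir_ksrp", dst = "MIR16", f1 = "lin:KSRPa"),
    rx("mir_deg", "d_mir16", src = "MIR16", f1 = "lin:MIR16"),
    # KSRP
    rx("ksrp_syn", "s_ksrp", dst = "KSRP"),
    rx("ksrp_deg", "d_ksrp", src = "KSRP", f1 = "lin:KSRP"),
    rx("ksrpa_deg", "d_ksrp", src = "KSRPa", f1 = "lin:KSRPa"),
    rx("ksrp_act", "k_ksrp_act", src = "KSRP", dst = "KSRPa",
       f1 = "lin:ATMa", f2 = "mm:KSRP:Km_ksrp"),
    rx("ksrpa_deact", "k_ksrpa_deact", src = "KSRPa", dst = "KSRP",
       f1 = "lin:KSRPa"),
    # CREB
    rx("creb_syn", "s_creb", dst = "CREB"),
    rx("creb_deg", "d_creb", src = "CREB", f1 = "lin:CREB"),
    rx("creba_deg", "d_creb", src = "CREBa", f1 = "lin:CREBa"),
    rx("creb_act", "k_creb_act", src = "CREB", dst = "CREBa",
       f1 = "lin:ATMa", f2 = "mm:CREB:Km_creb"),
    rx("creba_deact", "k_creba_deact", src = "CREBa", dst = "CREB",
       f1 = "lin:CREBa"),
    # NF-kB shuttling
    rx("nfkb_syn", "s_nfkb", dst = "NFKB_cyt"),
    rx("nfkbc_deg", "d_nfkb", src = "NFKB_cyt", f1 = "lin:NFKB_cyt"),
    rx("nfkbn_deg", "d_nfkb", src = "NFKB_nuc", f1 = "lin:NFKB_nuc"),
    rx("nfkb_import", "k_nf_imp", src = "NFKB_cyt", dst = "NFKB_nuc",
       f1 = "lin:NFKB_cyt", f2 = "inh:IKB:K_nf_ikb", transport = TRUE),
    rx("nfkb_export", "k_nf_exp", src = "NFKB_nuc", dst = "NFKB_cyt",
       f1 = "lin:NFKB_nuc", f2 = "lin:IKB", transport = TRUE),
    # IkB
    rx("ikb_syn_0", "s_ikb0", dst = "IKB"),
    rx("ikb_syn_nf", "s_ikb_nf", dst = "IKB", f1 = "lin:NFKB_nuc"),
    rx("ikb_deg", "d_ikb", src = "IKB", f1 = "lin:IKB"),
    rx("ikb_deg_ikk", "k_ikb_deg", src = "IKB",
       f1 = "lin:IKKa", f2 = "lin:IKB"),
    # IKK
    rx("ikk_syn", "s_ikk", dst = "IKKn"),
    rx("ikkn_deg", "d_ikk", src = "IKKn", f1 = "lin:IKKn"),
    rx("ikka_deg", "d_ikk", src = "IKKa", f1 = "lin:IKKa"),
    rx("ikk_act_r", "k_ikk_act_r", src = "IKKn", dst = "IKKa",
       f1 = "recept", f2 = "lin:IKKn", f3 = "inh:A20:K_a20"),
    rx("ikk_act_atm", "k_ikk_act_atm", src = "IKKn", dst = "IKKa",
       f1 = "lin:ATMa", f2 = "lin:IKKn", f3 = "inh:A20:K_a20"),
    rx("ikk_inact", "k_ikk_inact", src = "IKKa", dst = "IKKn",
       f1 = "lin:IKKa"),
    # A20
    rx("a20_syn_0", "s_a20_0", dst = "A20"),
    rx("a20_syn_nf", "s_a20_nf", dst = "A20", f1 = "lin:NFKB_nuc"),
    rx("a20_deg", "d_a20", src = "A20", f1 = "lin:A20"),
    # p21
    rx("p21m_syn_0", "s_p21m0", dst = "P21_mRNA"),
    rx("p21m_syn_p53", "s_p21m", dst = "P21_mRNA", f1 = "lin:P53a_nuc"),
    rx("p21m_deg", "d_p21m", src = "P21_mRNA", f1 = "lin:P21_mRNA"),
    rx("p21_syn", "k_p21_tr", dst = "P21", f1 = "lin:P21_mRNA"),
    rx("p21_deg", "d_p21", src = "P21", f1 = "lin:P21"),
    # Bax
    rx("baxm_syn_0", "s_baxm0", dst = "BAX_mRNA"),
    rx("baxm_syn_p53", "s_baxm", dst = "BAX_mRNA",
       f1 = "hill:P53a_nuc:K_baxm:n_baxm"),
    rx("baxm_deg", "d_baxm", src = "BAX_mRNA", f1 = "lin:BAX_mRNA"),
    rx("bax_syn", "k_bax_tr", dst = "BAX", f1 = "lin:BAX_mRNA"),
    rx("bax_deg", "d_bax", src = "BAX", f1 = "lin:BAX"))

  genes <- data.frame(
    name = c("g_wip1", "g_chk2", "g_atm"),
    q0 = c("q0_wip1", "q0_chk2", "q0_atm"),
    deact = c("d_g_wip1", "d_g_chk2", "d_g_atm"),
    stringsAsFactors = FALSE)

  gene_regs <- data.frame(
    gene = c("g_wip1", "g_wip1", "g_wip1", "g_chk2", "g_atm"),
    species = c("P53a_nuc", "CREBa", "NFKB_nuc", "P53a_nuc", "CREBa"),
    weight = c("q_p53_wip1", "q_creb_wip1", "q_nf_wip1", "q_p53_chk2",
               "q_creb_atm"),
    inh_species = c(NA, NA, "WIP1", "P53a_nuc", NA),
    inh_K = c(NA, NA, "K_wip_self", "K_chk2_p53", NA),
    stringsAsFactors = FALSE)

  ddr_model(species = species, params = params, reactions = reactions,
            genes = genes, gene_regs = gene_regs,
            dsb = list(k_per_gy = "dsb_k_per_gy",
                       background = "dsb_background",
                       vmax = "dsb_vmax", km = "dsb_km"),
            receptors = list(total = "n_tnfr", k_act = "k_rec_act",
                             k_deact = "k_rec_deact"),
            name = "atm_p53_nfkb_wip1")
}

#' Update parameter values in a model
#'
#' @param spec a `ddr_model`.
#' @param ... `name = value` pairs; names must exist in the parameter table.
#' @return the modified, revalidated model.
#' @export
set_params <- function(spec, ...) {
  upd <- list(...)
  idx <- match(names(upd), spec$params$name)
  if (anyNA(idx))
    stop("unknown parameter '", names(upd)[which(is.na(idx))[1]], "'",
         call. = FALSE)
  spec$params$value[idx] <- unlist(upd)
  validate_model(spec)
}
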