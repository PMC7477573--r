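# Shared fixtures: TFs, the study's gate circuits, hand-built unit
# operations, and independent oracles used to cross-check the implementation.

fix_tf <- list(
  I_plus = tf_spec("I_plus_YQR", "IPTG", "YQR", "X_plus"),
  I_plus_q = tf_spec("I_plus_YQR_q", "IPTG", "YQR", "X_plus",
                     expression_strength = 10),
  R_plus = tf_spec("R_plus_YQR", "d-ribose", "YQR", "X_plus"),
  I_anti = tf_spec("I_anti_HQN", "IPTG", "HQN", "X_anti"),
  R_anti = tf_spec("R_anti_HQN", "d-ribose", "HQN", "X_anti"),
  R_anti_KSL = tf_spec("R_anti_KSL", "d-ribose", "KSL", "X_anti"),
  F_anti_KSL = tf_spec("F_anti_KSL", "fructose", "KSL", "X_anti")
)

# The combinatorial gates assembled in the study, keyed by expected gate name.
study_gates <- function() {
  list(
    ANDp = circuit(channel("trc", operator_node("O1", "proximal")),
                   list(fix_tf$I_plus, fix_tf$R_plus), id = "ANDp"),
    ANDc_Osym = circuit(channel("trc", operator_node("Osym", "core")),
                        list(fix_tf$I_plus, fix_tf$R_plus), id = "ANDc_Osym"),
    ANDc_O1_default = circuit(channel("trc", operator_node("O1", "core")),
                              list(fix_tf$I_plus, fix_tf$R_plus),
                              id = "ANDc_O1"),
    ANDc_O1_strong = circuit(channel("trc", operator_node("O1", "core")),
                             list(fix_tf$I_plus_q, fix_tf$R_plus),
                             id = "ANDc_O1_strong"),
    NORp = circuit(channel("trc", operator_node("Ottg", "proximal")),
                   list(fix_tf$I_anti, fix_tf$R_anti), id = "NORp"),
    NORc = circuit(channel("trc", operator_node("Ottg", "core")),
                   list(fix_tf$I_anti, fix_tf$R_anti), id = "NORc"),
    NORcp = circuit(channel("trc", list(operator_node("Oagg", "core"),
                                        operator_node("Ottg", "proximal"))),
                    list(fix_tf$R_anti_KSL, fix_tf$I_anti), id = "NORcp"),
    NOR3 = circuit(channel("trc", list(operator_node("Oagg", "core"),
                                       operator_node("Ottg", "proximal"))),
                   list(fix_tf$R_anti_KSL, fix_tf$F_anti_KSL, fix_tf$I_anti),
                   id = "NOR3"),
    NAND = circuit(list(channel("trc", operator_node("Ottg", "core")),
                        channel("pL", operator_node("Oagg", "core"))),
                   list(fix_tf$I_anti, fix_tf$R_anti_KSL), id = "NAND"),
    XNOR = circuit(list(channel("trc", operator_node("Ottg", "proximal")),
                        channel("pL_mut", operator_node("Osym", "proximal"))),
                   list(fix_tf$I_anti, fix_tf$R_anti,
                        fix_tf$I_plus, fix_tf$R_plus), id = "XNOR")
  )
}

# Hand-built normalized unit operation with prescribed replicate vectors.
make_buo <- function(s_no, s_with, tf_id = "tf", operator = "O1",
                     position = "proximal") {
  structure(list(tf_id = tf_id, operator = operator, position = position,
                 s_no_ligand = s_no, s_with_ligand = s_with,
                 n = min(length(s_no), length(s_with)),
                 reference = "fixture"),
            class = "normalized_buo")
}

# A phenotype call with a forced phenotype (for card construction on
# degenerate inputs).
make_call <- function(buo, phenotype) {
  call <- classify_phenotype(buo)
  call$phenotype <- phenotype
  call
}

# Independent oracle for Boolean circuit output: walks the (tf, node)
# interaction tuples explicitly instead of going through binds()/
# operator_occupied()/channel_permitted().
oracle_circuit_output <- function(circ, ligands) {
  eff <- function(tf, nd) {
    ov <- circ$effectiveness_overrides
    if (!is.null(ov)) {
      hit <- ov$tf_id == tf$id & ov$operator == nd$operator &
        ov$position == nd$position
      if (any(hit)) return(ov$effective[which(hit)[1L]])
    }
    !(nd$position == "core" && nd$operator == "O1" &&
        tf$phenotype == "X_plus" && tf$dbd == "YQR" &&
        tf$rcd_ligand == "IPTG" && tf$expression_strength < 10)
  }
  for (ch in circ$channels) {
    blocked <- FALSE
    for (nd in ch$nodes) {
      for (tf in circ$tfs) {
        cog_dbd <- unname(circ$cognate_map[nd$operator])
        if (is.na(cog_dbd) || cog_dbd != tf$dbd) next
        bound <- switch(tf$phenotype,
                        X_plus = !(tf$rcd_ligand %in% ligands),
                        X_anti = tf$rcd_ligand %in% ligands,
                        X_super = TRUE, X_null = FALSE)
        if (bound && eff(tf, nd)) blocked <- TRUE
      }
    }
    if (!blocked) return(TRUE)   # some channel transmits
  }
  FALSE
}

# Random small circuit (1-3 TFs, 1-2 channels) for oracle-equivalence sweeps.
random_circuit <- function() {
  dbds <- c("YQR", "HQN", "KSL")
  phens <- c("X_plus", "X_anti", "X_super", "X_null")
  n_tf <- sample(1:3, 1)
  tfs <- lapply(seq_len(n_tf), function(i) {
    phen <- if (i == 1L) sample(c("X_plus", "X_anti"), 1) else sample(phens, 1)
    tf_spec(paste0("tf", i), sample(.buo_test_ligands, 1), sample(dbds, 1),
            phen, sample(c(1, 10), 1))
  })
  ops <- c("O1", "Osym", "Ottg", "Oagg")
  mk_channel <- function(prom) {
    n_nodes <- sample(1:2, 1)
    pos <- sample(c("core", "proximal"), n_nodes)
    nodes <- lapply(seq_len(n_nodes), function(j) {
      operator_node(sample(ops, 1), pos[j])
    })
    channel(prom, nodes)
  }
  n_ch <- sample(1:2, 1)
  chans <- if (n_ch == 1L) list(mk_channel("trc"))
           else list(mk_channel("trc"), mk_channel("pL"))
  circuit(chans, tfs)
}
.buo_test_ligands <- c("IPTG", "fructose", "d-ribose")

# Monte-Carlo permutation test on |mean difference| (the significance
# oracle for Welch's test).
perm_p <- function(a, b, n_perm = 4999L) {
  pooled <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    d <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1L) / (n_perm + 1L)
}

# Probability that n equiprobable draws from k labels cover all k labels,
# via the surjection recurrence (independent of inclusion-exclusion).
coverage_by_recurrence <- function(n, k) {
  if (n < k) return(0)
  surj <- matrix(0, nrow = n + 1L, ncol = k + 1L)
  surj[1L, 1L] <- 1   # surj(0, 0) = 1
  for (ni in 1:n) {
    for (ki in 1:min(ni, k)) {
      surj[ni + 1L, ki + 1L] <- ki * (surj[ni, ki + 1L] + surj[ni, ki])
    }
  }
  surj[n + 1L, k + 1L] / k^n
}

# Equal 4-way genotype mix covering all phenotypes, for sort simulations.
four_way_mix <- function(ligand = "fructose") {
  mk <- function(id, phen) {
    profile_from_phenotype(tf_spec(id, ligand, "YQR", phen), "O1", "proximal")
  }
  list(list(profile = mk("g_plus", "X_plus"), fraction = 0.25),
       list(profile = mk("g_anti", "X_anti"), fraction = 0.25),
       list(profile = mk("g_super", "X_super"), fraction = 0.25),
       list(profile = mk("g_null", "X_null"), fraction = 0.25))
}
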