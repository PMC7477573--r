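test_that("phenotypes map onto expression profiles with correct levels", {
  params <- profile_defaults()  # ON 0.9, proximal fold 10

  nul <- profile_from_phenotype(
    tf_spec("n", "IPTG", "YQR", "X_null"), "O1", "proximal")
  expect_gte(nul$level_no_ligand, 0.9)
  expect_equal(nul$level_no_ligand, nul$level_with_ligand)

  anti <- profile_from_phenotype(
    tf_spec("a", "IPTG", "YQR", "X_anti"), "O1", "proximal", params = params)
  expect_equal(anti$level_no_ligand, 0.9)
  expect_equal(anti$level_with_ligand, 0.09)  # ON / fold = 0.9 / 10

  sup <- profile_from_phenotype(
    tf_spec("s", "IPTG", "YQR", "X_super"), "O1", "proximal")
  expect_equal(sup$level_no_ligand, 0.03)
  expect_equal(sup$level_with_ligand, 0.03)

  # non-cognate pairing: essentially unregulated in both states
  nc <- profile_from_phenotype(
    tf_spec("a", "IPTG", "YQR", "X_anti"), "Oagg", "proximal", cognate = FALSE)
  expect_gte(nc$level_no_ligand, 0.9)
  expect_equal(nc$level_no_ligand, nc$level_with_ligand)

  # core position gives at least the proximal dynamic range
  core <- profile_from_phenotype(
    tf_spec("a", "IPTG", "YQR", "X_anti"), "O1", "core", params = params)
  dr <- function(p) p$level_no_ligand / p$level_with_ligand
  expect_gte(dr(core), dr(anti))
})

test_that("plate simulation honors replicate structure, controls and seeds", {
  prs <- list(
    profile_from_phenotype(fix_tf$I_anti, "Ottg", "proximal"),
    profile_from_phenotype(fix_tf$R_anti_KSL, "Oagg", "core"))
  pl <- simulate_buo_plate(prs, noise_model(), n_reps = 6, seed = 11)

  tf_wells <- pl[pl$sample_type == "tf", ]
  counts <- table(tf_wells$tf_id, tf_wells$ligands != "")
  expect_true(all(counts == 6))  # 6 replicates per TF per ligand state

  # lac_null controls present in every (operator, position) stratum, blanks present
  strata <- unique(tf_wells[, c("operator", "position")])
  nulls <- pl[pl$sample_type == "lac_null", c("operator", "position")]
  for (i in seq_len(nrow(strata))) {
    expect_true(any(nulls$operator == strata$operator[i] &
                      nulls$position == strata$position[i]))
  }
  expect_gt(sum(pl$sample_type == "blank"), 0)

  # determinism: identical seed, identical plate
  expect_identical(pl, simulate_buo_plate(prs, noise_model(), n_reps = 6,
                                          seed = 11))
  pl2 <- simulate_buo_plate(prs, noise_model(), n_reps = 6, seed = 12)
  expect_false(identical(pl$fluorescence, pl2$fluorescence))

  expect_error(simulate_buo_plate(prs, noise_model(), n_reps = 1, seed = 1),
               "n_reps")
})

test_that("zero-noise plates recover configured levels exactly", {
  prs <- list(profile_from_phenotype(fix_tf$I_anti, "Ottg", "proximal"),
              profile_from_phenotype(fix_tf$I_plus, "O1", "proximal"))
  pl <- simulate_buo_plate(prs, noise_model(cv_fluorescence = 0, cv_od = 0),
                           seed = 1)
  std <- standardize_to_max(normalize_plate(pl))
  buos <- collect_buos(std)
  lv <- lapply(buos, function(b) c(mean(b$s_no_ligand), mean(b$s_with_ligand)))
  names(lv) <- vapply(buos, `[[`, "", "tf_id")
  expect_equal(lv[["I_anti_HQN"]], c(0.9, 0.09), tolerance = 1e-12)
  expect_equal(lv[["I_plus_YQR"]], c(0.09, 0.9), tolerance = 1e-12)
})

test_that("mean recovered fold change is unbiased at default noise", {
  # Monte-Carlo parameter recovery: fold-10 profile, cv 0.05, n = 6
  pr <- profile_from_phenotype(fix_tf$I_anti, "Ottg", "proximal")
  nm <- noise_model(cv_fluorescence = 0.05, cv_od = 0.05)
  folds <- vapply(1:100, function(s) {
    pl <- simulate_buo_plate(list(pr), nm, seed = 1000 + s)
    b <- collect_buos(standardize_to_max(normalize_plate(pl)))[[1]]
    mean(b$s_no_ligand) / mean(b$s_with_ligand)
  }, 0)
  se <- sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 10), 3 * se)
})

test_that("gate plates enumerate the condition power set", {
  pl2 <- simulate_gate_plate(study_gates()$NAND, noise_model(), seed = 3)
  gate <- pl2[pl2$sample_type == "gate", ]
  expect_equal(length(unique(gate$ligands)), 4)       # 2^2 conditions
  expect_true(all(table(gate$ligands) == 12))         # 12 replicates each

  pl3 <- simulate_gate_plate(study_gates()$NOR3, noise_model(), seed = 3)
  expect_equal(length(unique(pl3$ligands[pl3$sample_type == "gate"])), 8)

  # zero-noise NAND: 3 conditions at the high plateau, one at leak
  pl0 <- simulate_gate_plate(study_gates()$NAND,
                             noise_model(cv_fluorescence = 0, cv_od = 0),
                             seed = 1)
  g0 <- normalize_plate(pl0)
  g0 <- g0[g0$sample_type == "gate", ]
  m <- tapply(g0$normalized, g0$ligands, mean)
  hi <- m >= 0.5 * max(m)
  expect_equal(sum(hi), 3)
  expect_equal(names(m)[!hi], "IPTG;d-ribose")
})

test_that("cytometry samples follow the log-normal single-cell model", {
  pr9 <- profile_from_phenotype(fix_tf$I_anti, "Ottg", "proximal")  # 0.9 / 0.09
  s_hi <- simulate_cytometry(pr9, character(0), seed = 5)
  expect_gte(nrow(s_hi), 25000)
  s_lo <- simulate_cytometry(pr9, "IPTG", n_events = 25000, seed = 6)
  ratio <- fitc_geometric_mean(s_hi) / fitc_geometric_mean(s_lo)
  expect_gt(ratio, 8)   # level 0.9 vs 0.09 differ ~10-fold
  expect_lt(ratio, 12)

  # level-0 profile sits at the autofluorescence floor
  p0 <- pr9; p0$level_no_ligand <- 0
  s0 <- simulate_cytometry(p0, character(0), n_events = 10000, seed = 7)
  cyt <- cytometer_defaults()
  expect_equal(fitc_geometric_mean(s0), cyt$autofluor_gm, tolerance = 0.05)

  expect_identical(simulate_cytometry(pr9, "IPTG", 5000, seed = 9),
                   simulate_cytometry(pr9, "IPTG", 5000, seed = 9))
})

test_that("sort libraries carry labels and per-genotype distributions", {
  mix <- four_way_mix("fructose")
  s <- simulate_sort_library(mix, condition = "fructose", n_events = 50000,
                             seed = 21)
  expect_equal(nrow(s), 50000)
  g <- gate_singlets(s)
  hi <- tapply(g$fitc_a >= 1e4, g$genotype, mean)
  # with ligand: only the nonfunctional and the induced repressor are bright
  expect_gt(hi[["g_null"]], 0.9)
  expect_gt(hi[["g_plus"]], 0.9)
  expect_lt(hi[["g_anti"]], 0.1)
  expect_lt(hi[["g_super"]], 0.1)

  bad <- mix; bad[[1]]$fraction <- 0.5
  expect_error(simulate_sort_library(bad, n_events = 100), "sum to 1")

  # pure nonfunctional library: high in both conditions
  pure <- list(list(profile = mix[[4]]$profile, fraction = 1))
  for (cond in list(character(0), "fructose")) {
    sp <- gate_singlets(simulate_sort_library(pure, cond, 10000, seed = 2))
    expect_gt(mean(sp$fitc_a >= 1e4), 0.95)
  }
})
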