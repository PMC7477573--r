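test_that("performance cards compute fold metrics with a documented floor", {
  set.seed(77)
  j <- function(m, n = 6) m * (1 + rnorm(n, 0, 0.02))
  anti <- make_buo(j(0.9), j(0.09))
  card <- performance_card(anti)
  expect_equal(card$dynamic_range, mean(anti$s_no_ligand) / mean(anti$s_with_ligand))
  expect_equal(card$dynamic_range, 10, tolerance = 0.1)
  expect_equal(card$unit, "AIU")
  expect_false(card$floor_applied)

  # degenerate equal states: dynamic range collapses to 1
  deg <- make_buo(rep(0.4, 6), rep(0.4, 6))
  card_deg <- performance_card(deg, make_call(deg, "X_anti"))
  expect_equal(card_deg$dynamic_range, 1)

  # all-zero OFF state: floor applied and flagged
  z <- make_buo(j(0.9), rep(0, 6))
  card_z <- performance_card(z, make_call(z, "X_anti"))
  expect_true(card_z$floor_applied)
  expect_equal(card_z$dynamic_range, mean(z$s_no_ligand) / 0.005)

  # lac_null-level unit: fraction of maximum ~ 1, no fold metrics
  nul <- make_buo(j(1), j(1))
  card_n <- performance_card(nul)
  expect_equal(card_n$fmo_on, 1, tolerance = 0.05)
  expect_true(is.na(card_n$dynamic_range))
})

test_that("dynamic range is monotone non-increasing in the OFF level", {
  on <- rep(0.9, 6)
  drs <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.45), function(off) {
    b <- make_buo(on, rep(off, 6))
    performance_card(b, make_call(b, "X_anti"))$dynamic_range
  }, 0)
  expect_true(all(diff(drs) <= 0))
})

test_that("card metrics are invariant to a global fluorescence rescale", {
  pr <- profile_from_phenotype(fix_tf$I_anti, "Ottg", "proximal")
  pl <- simulate_buo_plate(list(pr), noise_model(), seed = 31)
  card1 <- performance_card(collect_buos(standardize_to_max(normalize_plate(pl)))[[1]])
  pl$fluorescence <- pl$fluorescence * 7.3
  card2 <- performance_card(collect_buos(standardize_to_max(normalize_plate(pl)))[[1]])
  expect_equal(card1$dynamic_range, card2$dynamic_range)
  expect_equal(card1$ru_raw, card2$ru_raw)
  expect_equal(card1$fmo_on, card2$fmo_on)
})

test_that("traceability against the reference is exactly unity, and scales", {
  set.seed(88)
  j <- function(m) m * (1 + rnorm(6, 0, 0.02))
  ref_buo <- make_buo(j(0.09), j(0.9), tf_id = "I_plus_YQR")
  ref <- performance_card(ref_buo)
  expect_equal(ref$phenotype, "X_plus")
  tr <- traceability_scores(ref, ref)
  expect_identical(tr$traceability_dr, 1)
  expect_identical(tr$traceability_ru, 1)
  expect_equal(tr$unit, "IU")

  # anti-repressor with the same dynamic range scores ~1 AIU
  anti <- performance_card(make_buo(j(0.9), rep(0.9 / ref$dynamic_range, 6)))
  tra <- traceability_scores(anti, ref)
  expect_equal(tra$traceability_dr, 1, tolerance = 0.05)
  expect_equal(tra$unit, "AIU")

  # doubled dynamic range scores 2
  dbl_buo <- make_buo(rep(0.9, 6), rep(0.9 / (2 * ref$dynamic_range), 6))
  dbl <- performance_card(dbl_buo, make_call(dbl_buo, "X_anti"))
  expect_equal(traceability_scores(dbl, ref)$traceability_dr, 2,
               tolerance = 1e-6)

  expect_error(traceability_scores(ref, anti), "BUFFER")
})

test_that("pairing compatibility applies the RU-ratio and proximity rules", {
  mk_card <- function(s_no, s_with) {
    b <- make_buo(rep(s_no, 6), rep(s_with, 6))
    performance_card(b, make_call(b, "X_anti"))
  }
  # RU 1 vs 12: extreme repression-unit difference -> incompatible
  a <- mk_card(1.0, 0.1)          # RU = 1
  b <- mk_card(1 / 12, 1 / 120)   # RU = 12
  expect_equal(pairing_compatibility(a, b)$verdict, "incompatible")

  # AIU 6, RU 5, DR 6: ON state attenuated toward super-repression -> caution
  c1 <- mk_card(0.2, 0.2 / 6)     # AIU 6, RU 5
  c2 <- mk_card(0.9, 0.09)
  rep_c <- pairing_compatibility(c1, c2)
  expect_true(rep_c$proximity_flag)
  expect_equal(rep_c$verdict, "caution")

  # two reference-like cards are compatible
  expect_equal(pairing_compatibility(c2, mk_card(0.85, 0.08))$verdict,
               "compatible")
})

test_that("reference ranking counts units at or above the reference range", {
  mk_card <- function(dr, id, pos = "proximal") {
    b <- make_buo(rep(0.9, 4), rep(0.9 / dr, 4), tf_id = id, position = pos)
    performance_card(b, make_call(b, "X_anti"))
  }
  ref <- mk_card(10, "ref")
  below <- lapply(1:36, function(i) mk_card(2 + i %% 7, paste0("lo", i)))
  above <- lapply(1:9, function(i) mk_card(10 + i, paste0("hi", i),
                                           pos = if (i <= 4) "core" else "proximal"))
  rk <- rank_vs_reference(c(below, above), ref)
  expect_equal(rk$count, 9)
  expect_equal(unname(rk$count_by_position["core"]), 4)
  expect_true(all(diff(rk$table$dynamic_range) <= 0))  # ordered descending

  rk0 <- rank_vs_reference(below, ref)
  expect_equal(rk0$count, 0)
  # >= comparison: adding a card exactly at the reference increments the count
  rk1 <- rank_vs_reference(c(below, list(mk_card(10, "tie"))), ref)
  expect_equal(rk1$count, 1)
})

test_that("assay concordance reports R-squared and fit sign", {
  ident <- data.frame(buo_id = letters[1:4], state = "no", value = c(1, 2, 3, 4))
  conc <- assay_concordance(ident, ident)
  expect_equal(conc$r_squared, 1)
  expect_equal(conc$slope, 1)

  anti <- ident; anti$value <- rev(ident$value)
  expect_lt(assay_concordance(ident, anti)$slope, 0)

  expect_error(assay_concordance(ident[1:2, ], ident[1:2, ]), ">= 3")
})

test_that("plate and cytometry summaries agree for matched unit operations", {
  prs <- list(profile_from_phenotype(fix_tf$I_anti, "Ottg", "proximal"),
              profile_from_phenotype(fix_tf$R_anti_KSL, "Oagg", "core"),
              profile_from_phenotype(fix_tf$I_plus, "O1", "proximal"))
  pl <- simulate_buo_plate(prs, noise_model(), seed = 61)
  buos <- collect_buos(standardize_to_max(normalize_plate(pl)))
  id_of <- function(b) paste(b$tf_id, b$operator, b$position, sep = "|")
  plate_vals <- do.call(rbind, lapply(buos, function(b) data.frame(
    buo_id = id_of(b), state = c("no", "with"),
    value = c(mean(b$s_no_ligand), mean(b$s_with_ligand)))))
  set.seed(62)
  cyt_vals <- do.call(rbind, lapply(buos, function(b) {
    pr <- Filter(function(p) p$tf_id == b$tf_id, prs)[[1]]
    data.frame(buo_id = id_of(b), state = c("no", "with"),
               value = c(fitc_geometric_mean(simulate_cytometry(pr, character(0), 8000)),
                         fitc_geometric_mean(simulate_cytometry(pr, pr$ligand, 8000))))
  }))
  conc <- assay_concordance(plate_vals, cyt_vals)
  expect_gt(conc$r_squared, 0.9)
  expect_gt(conc$slope, 0)
})

test_that("cards serialize to JSON and a flat table", {
  set.seed(99)
  b <- make_buo(0.9 * (1 + rnorm(6, 0, 0.02)), 0.09 * (1 + rnorm(6, 0, 0.02)))
  cards <- list(performance_card(b))
  tab <- cards_table(cards)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$dynamic_range, cards[[1]]$dynamic_range)
  parsed <- jsonlite::fromJSON(cards_to_json(cards), simplifyVector = FALSE)
  expect_equal(parsed[[1]]$dynamic_range, cards[[1]]$dynamic_range)
})
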