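test_that("binding follows phenotype truth semantics", {
  expect_true(binds(fix_tf$I_anti, "IPTG"))
  expect_false(binds(fix_tf$I_anti, character(0)))
  expect_true(binds(fix_tf$I_plus, character(0)))     # repressor binds until induced
  expect_false(binds(fix_tf$I_plus, "IPTG"))
  expect_true(binds(tf_spec("s", "IPTG", "YQR", "X_super"), "fructose"))
  expect_false(binds(tf_spec("n", "IPTG", "YQR", "X_null"), "IPTG"))
})

test_that("shared-operator occupancy is a disjunction over cognate TFs", {
  norp <- study_gates()$NORp
  node <- norp$channels[[1]]$nodes[[1]]
  expect_true(operator_occupied(node, norp, "IPTG"))
  expect_true(operator_occupied(node, norp, "d-ribose"))
  expect_true(operator_occupied(node, norp, c("IPTG", "d-ribose")))
  expect_false(operator_occupied(node, norp, character(0)))

  andp <- study_gates()$ANDp
  node_a <- andp$channels[[1]]$nodes[[1]]
  expect_false(operator_occupied(node_a, andp, c("IPTG", "d-ribose")))
  expect_true(operator_occupied(node_a, andp, "IPTG"))  # R_plus still bound

  # no cognate TF -> never occupied; empty channel always permits
  lone <- circuit(channel("trc", operator_node("Ogta", "proximal")),
                  list(fix_tf$I_anti))
  expect_false(operator_occupied(lone$channels[[1]]$nodes[[1]], lone, "IPTG"))
  empty_ch <- channel("trc", list())
  expect_true(channel_permitted(empty_ch, lone, "IPTG"))
})

test_that("series channels conjoin and parallel circuits disjoin", {
  norcp <- study_gates()$NORcp
  ch <- norcp$channels[[1]]
  expect_true(channel_permitted(ch, norcp, character(0)))
  expect_false(channel_permitted(ch, norcp, "IPTG"))
  expect_false(channel_permitted(ch, norcp, "d-ribose"))

  nand <- study_gates()$NAND
  expect_true(circuit_output(nand, "IPTG"))     # other channel still open
  expect_false(circuit_output(nand, c("IPTG", "d-ribose")))

  single <- circuit(channel("trc", operator_node("Ottg", "proximal")),
                    list(fix_tf$I_anti))
  expect_equal(circuit_output(single, "IPTG"),
               channel_permitted(single$channels[[1]], single, "IPTG"))
})

test_that("predicted truth tables name the study's gates", {
  expected <- c(ANDp = "AND", ANDc_Osym = "AND",
                ANDc_O1_default = "single-input (d-ribose BUFFER)",
                ANDc_O1_strong = "AND",
                NORp = "NOR", NORc = "NOR", NORcp = "NOR", NOR3 = "NOR",
                NAND = "NAND", XNOR = "XNOR")
  gates <- study_gates()
  for (nm in names(expected)) {
    expect_equal(classify_gate(predict_truth_table(gates[[nm]])),
                 unname(expected[nm]), label = nm)
  }
  tt3 <- predict_truth_table(gates$NOR3)
  expect_equal(nrow(tt3), 8)
  expect_equal(sum(tt3$output), 1)   # three-input NOR: true only with no ligand
  expect_true(tt3$output[tt3$condition == ""])

  # an all-nonfunctional circuit is constitutively on
  nulls <- circuit(channel("trc", operator_node("O1", "proximal")),
                   list(tf_spec("n1", "IPTG", "YQR", "X_null")),
                   inputs = "IPTG")
  expect_equal(classify_gate(predict_truth_table(nulls)), "constant 1")
})

test_that("quantitative output follows the product/max composition model", {
  norcp <- study_gates()$NORcp
  params <- profile_defaults(on_level = 0.9)
  profiles <- buometry:::default_circuit_profiles(norcp, params)
  # both nodes free: 0.9 * 0.9
  expect_equal(quantitative_output(norcp, character(0), profiles, params), 0.81)
  # occupied core node bounds the channel by its leak
  lev <- quantitative_output(norcp, "d-ribose", profiles, params)
  expect_lte(lev, 0.05)

  # boolean threshold at 0.5 agrees with the logical model on all study gates
  for (circ in study_gates()) {
    tt <- predict_truth_table(circ)
    expect_equal(tt$level > 0.5, tt$output, label = circ$id)
  }

  expect_error(
    quantitative_output(norcp, "IPTG", profiles = list()), "missing")
})

test_that("composition model equals the brute-force binding-state oracle", {
  set.seed(515)
  for (i in 1:80) {
    circ <- random_circuit()
    for (lig_set in buometry:::ligand_subsets(.buo_test_ligands)) {
      expect_equal(circuit_output(circ, lig_set),
                   oracle_circuit_output(circ, lig_set),
                   label = sprintf("random circuit %d, {%s}", i,
                                   paste(lig_set, collapse = ",")))
    }
  }
})

test_that("De Morgan and series-parallel dualities hold", {
  # PARA of two NOT channels == complement of input AND (i.e. NAND)
  tt <- predict_truth_table(study_gates()$NAND)
  and_in <- tt$IPTG & tt$`d-ribose`
  expect_equal(tt$output, !and_in)

  # SE-PA of two BUFFERs -> AND; SE-PA of two NOTs -> NOR
  expect_equal(classify_gate(predict_truth_table(study_gates()$ANDp)), "AND")
  expect_equal(classify_gate(predict_truth_table(study_gates()$NORp)), "NOR")
})

test_that("gate evaluation binarizes conditions by Tukey group membership", {
  nand0 <- simulate_gate_plate(study_gates()$NAND,
                               noise_model(cv_fluorescence = 0, cv_od = 0),
                               seed = 2)
  ev0 <- evaluate_gate(nand0)
  expect_equal(ev0$matched_gate, "NAND")
  expect_lt(ev0$anova_p, 0.01)
  expect_equal(max(ev0$nou$mean), 1)  # N.O.U. anchored at the max condition

  nand <- simulate_gate_plate(study_gates()$NAND, noise_model(), seed = 3)
  ev <- evaluate_gate(nand, expected = predict_truth_table(study_gates()$NAND))
  expect_equal(ev$matched_gate, "NAND")
  expect_true(ev$matches_expected)

  # flat plate: no separation, constant call
  flat <- circuit(channel("trc", operator_node("Ogta", "proximal")),
                  list(tf_spec("n", "IPTG", "YQR", "X_null")),
                  inputs = c("IPTG", "d-ribose"))
  ev_flat <- evaluate_gate(simulate_gate_plate(flat, noise_model(), seed = 4))
  expect_gt(ev_flat$anova_p, 0.01)
  expect_equal(ev_flat$matched_gate, "constant")
})

test_that("circuits round-trip through JSON", {
  circ <- study_gates()$XNOR
  js <- circuit_to_json(circ)
  back <- circuit_from_json(js)
  expect_equal(back$inputs, circ$inputs)
  expect_equal(length(back$tfs), length(circ$tfs))
  tt1 <- predict_truth_table(circ)
  tt2 <- predict_truth_table(back)
  expect_equal(tt2$output, tt1$output)
  expect_equal(tt2$level, tt1$level)

  ov <- data.frame(tf_id = "I_plus_YQR", operator = "Osym",
                   position = "core", effective = FALSE,
                   stringsAsFactors = FALSE)
  circ_ov <- circuit(channel("trc", operator_node("Osym", "core")),
                     list(fix_tf$I_plus, fix_tf$R_plus),
                     effectiveness_overrides = ov)
  expect_equal(classify_gate(predict_truth_table(circ_ov)),
               "single-input (d-ribose BUFFER)")
  back_ov <- circuit_from_json(circuit_to_json(circ_ov))
  expect_equal(classify_gate(predict_truth_table(back_ov)),
               "single-input (d-ribose BUFFER)")
})
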