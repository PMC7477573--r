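#' Evaluate a measured logic gate
#'
#' Normalizes a gate plate (blank subtraction, density normalization), scales
#' each ligand-condition mean to the highest condition mean (normalized
#' output units, N.O.U., so the maximum condition is 1 by construction), then
#' tests for state separation with a one-way ANOVA across conditions followed
#' by a post-hoc Tukey HSD (default alpha 0.01). Conditions in the same Tukey
#' group as the maximum are binarized to 1, those in the same group as the
#' minimum to 0; a condition separated from both is indeterminate. The
#' binarized pattern is matched to a canonical gate name with
#' [classify_gate()]. If the ANOVA finds no separation at all, the gate is
#' `"constant"`. When replicate variation is numerically zero (noise-free
#' simulations), conditions are binarized by direct comparison of means
#' instead.
#'
#' @param plate A gate `sim_plate` ([simulate_gate_plate()]) or compatible
#'   CSV data frame.
#' @param expected Optional expected `truth_table`; when given, the
#'   evaluation reports whether the measured pattern matches it.
#' @param alpha Significance level for gate statistics (default 0.01).
#' @return A list of class `gate_eval` with `nou` (per-condition means, SDs
#'   and binary state), `anova_p`, `tukey_groups` (same-as-max /
#'   same-as-min membership), `matched_gate`, and `matches_expected` (when
#'   `expected` is supplied).
#' @export
evaluate_gate <- function(plate, expected = NULL, alpha = 0.01) {
  norm <- normalize_plate(plate)
  gate <- norm[norm$sample_type == "gate", , drop = FALSE]
  if (nrow(gate) == 0L) {
    # plates assembled outside simulate_gate_plate may label wells "tf"
    gate <- norm[norm$sample_type == "tf", , drop = FALSE]
  }
  if (nrow(gate) == 0L) stop("plate contains no gate wells", call. = FALSE)
  cond <- factor(gate$ligands)
  reps <- table(cond)
  if (any(reps < 2L)) {
    stop("every condition needs >= 2 replicates", call. = FALSE)
  }
  means <- tapply(gate$normalized, cond, mean)
  sds <- tapply(gate$normalized, cond, sd)
  nou <- means / max(means)
  labels <- names(means)

  imax <- which.max(means)
  imin <- which.min(means)
  resid_sd <- sqrt(mean(tapply(gate$normalized, cond, var)))
  scale <- max(abs(means))

  if (resid_sd < 1e-9 * scale) {
    # Degenerate (noise-free) replicates: binarize by direct comparison.
    anova_p <- if (diff(range(means)) < 1e-9 * scale) 1 else 0
    same_max <- abs(means - means[imax]) < 1e-6 * scale
    same_min <- abs(means - means[imin]) < 1e-6 * scale
  } else {
    fit <- aov(normalized ~ cond, data = data.frame(
      normalized = gate$normalized, cond = cond))
    anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$cond
    pair_p <- function(a, b) {
      if (a == b) return(1)
      rn <- rownames(tk)
      hit <- rn == paste(a, b, sep = "-") | rn == paste(b, a, sep = "-")
      tk[hit, "p adj"]
    }
    same_max <- vapply(labels, function(l) pair_p(l, labels[imax]) > alpha, TRUE)
    same_min <- vapply(labels, function(l) pair_p(l, labels[imin]) > alpha, TRUE)
  }

  if (is.na(anova_p)) anova_p <- 1
  if (anova_p >= alpha || all(same_max & same_min)) {
    state <- rep(TRUE, length(means))   # nominal: everything at the plateau
    matched <- "constant"
  } else {
    state <- rep(NA, length(means))
    state[same_max & !same_min] <- TRUE
    state[same_min & !same_max] <- FALSE
    inputs <- sort(unique(unlist(lapply(labels, condition_ligands))))
    tbl <- as.data.frame(do.call(rbind, lapply(labels, function(l) {
      inputs %in% condition_ligands(l)
    })))
    names(tbl) <- inputs
    tbl$output <- state
    attr(tbl, "inputs") <- inputs
    matched <- if (anyNA(state)) "unclassified" else classify_gate(tbl)
  }

  res <- structure(list(
    nou = data.frame(condition = labels, mean = as.numeric(nou),
                     sd = as.numeric(sds / max(means)),
                     state = state, stringsAsFactors = FALSE),
    anova_p = anova_p,
    tukey_groups = data.frame(condition = labels,
                              same_as_max = as.logical(same_max),
                              same_as_min = as.logical(same_min)),
    matched_gate = matched,
    alpha = alpha
  ), class = "gate_eval")

  if (!is.null(expected)) {
    idx <- match(expected$condition, res$nou$condition)
    res$matches_expected <- !anyNA(idx) && !anyNA(res$nou$state[idx]) &&
      all(res$nou$state[idx] == expected$output)
  }
  res
}

#' @export
print.gate_eval <- function(x, ...) {
  cat(sprintf("<gate_eval> matched gate: %s (ANOVA p = %.3g, alpha = %g)\n",
              x$matched_gate, x$anova_p, x$alpha))
  print(x$nou, row.names = FALSE)
  invisible(x)
}
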