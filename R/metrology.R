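#' Performance card for a unit operation
#'
#' Standardizes a unit operation's two ligand states into a card of
#' performance metrics. The ON state is the high-output state and the OFF
#' state the low-output state, assigned by phenotype (for an anti-repressor
#' the ON state is without ligand; for a repressor, with ligand). Reported
#' metrics:
#' \itemize{
#'   \item `fmo_on`, `fmo_off` -- fraction of maximum output (stratum
#'     maximum, i.e. the `lac_null` level, anchored at `max_output` r.f.u.).
#'   \item `dynamic_range` -- fold change ON/OFF (fold anti-induction for an
#'     anti-repressor, fold induction for a repressor); the OFF mean is
#'     floored at `floor` (detection limit) and flagged when the floor binds.
#'   \item `aiu_or_iu_raw` -- the dynamic range expressed in the card's raw
#'     units: anti-induction units (AIU) for `X_anti`, induction units (IU)
#'     for `X_plus`.
#'   \item `ru_raw` -- repression units: attenuation of the no-ligand state
#'     relative to maximum, `1 / s_no_ligand`. For an anti-repressor RU
#'     approaches AIU exactly when its ON state is attenuated toward
#'     super-repression.
#' }
#' Cards for `X_super`/`X_null` units carry levels only (fold metrics `NA`).
#'
#' @param buo A `normalized_buo` ([collect_buos()]).
#' @param phenotype A `phenotype_call`, or `NULL` to classify internally.
#' @param max_output Raw-fluorescence anchor of the maximum (75,000 r.f.u.).
#' @param floor Denominator floor in fraction-of-maximum units (detection
#'   limit, default 0.005).
#' @return An object of class `performance_card`.
#' @export
performance_card <- function(buo, phenotype = NULL, max_output = 75000,
                             floor = 0.005) {
  stopifnot(inherits(buo, "normalized_buo"))
  if (is.null(phenotype)) phenotype <- classify_phenotype(buo)
  stopifnot(inherits(phenotype, "phenotype_call"))
  m_no <- mean(buo$s_no_ligand)
  m_with <- mean(buo$s_with_ligand)
  phen <- phenotype$phenotype

  if (phen == "X_plus") {
    on <- buo$s_with_ligand; off <- buo$s_no_ligand
  } else {
    # X_anti ON state is without ligand; for X_super/X_null the split is
    # nominal (levels are symmetric).
    on <- buo$s_no_ligand; off <- buo$s_with_ligand
  }
  floored <- mean(off) < floor
  dr <- if (phen %in% c("X_plus", "X_anti")) {
    mean(on) / max(mean(off), floor)
  } else NA_real_
  ru <- 1 / max(m_no, floor)
  structure(list(
    buo_id = paste(buo$tf_id, buo$operator, buo$position, sep = "|"),
    tf_id = buo$tf_id, operator = buo$operator, position = buo$position,
    phenotype = phen,
    s_on = c(mean = mean(on), sd = sd(on)),
    s_off = c(mean = mean(off), sd = sd(off)),
    fmo_on = mean(on), fmo_off = mean(off),
    raw_on = mean(on) * max_output, raw_off = mean(off) * max_output,
    dynamic_range = dr,
    repression_strength = ru,
    aiu_or_iu_raw = dr,
    ru_raw = ru,
    unit = switch(phen, X_anti = "AIU", X_plus = "IU", NA_character_),
    floor = floor, floor_applied = floored,
    max_output = max_output
  ), class = "performance_card")
}

#' @export
print.performance_card <- function(x, ...) {
  cat(sprintf("<performance_card> %s [%s]\n", x$buo_id, x$phenotype))
  cat(sprintf("  ON %.3f +/- %.3f | OFF %.3f +/- %.3f (F.M.O.)\n",
              x$s_on[["mean"]], x$s_on[["sd"]],
              x$s_off[["mean"]], x$s_off[["sd"]]))
  if (!is.na(x$dynamic_range)) {
    cat(sprintf("  dynamic range %.2f %s | RU %.2f%s\n", x$dynamic_range,
                x$unit, x$ru_raw,
                if (x$floor_applied) " (OFF state at detection floor)" else ""))
  }
  invisible(x)
}

#' Traceability scores against the reference unit operation
#'
#' Compares a card's performance metrics to the reference BUFFER unit
#' operation (the wild-type repressor on its natural operator, proximal
#' position) as ratios: `traceability_dr = dynamic_range / reference
#' dynamic_range` (reported as AIU for an anti-repressor card, IU for a
#' repressor card) and `traceability_ru = repression_strength / reference
#' repression_strength`. The reference against itself scores exactly
#' (1.0, 1.0).
#'
#' @param card A `performance_card` with fold metrics.
#' @param reference The reference `performance_card` (a BUFFER, `X_plus`).
#' @return A list `(traceability_dr, traceability_ru, unit)`.
#' @export
traceability_scores <- function(card, reference) {
  stopifnot(inherits(card, "performance_card"),
            inherits(reference, "performance_card"))
  if (!identical(reference$phenotype, "X_plus")) {
    stop("the reference card must be a BUFFER (X_plus) unit operation",
         call. = FALSE)
  }
  if (!is.finite(reference$dynamic_range) || reference$dynamic_range <= 0) {
    stop("reference dynamic range must be positive", call. = FALSE)
  }
  if (!is.finite(card$dynamic_range)) {
    stop("card carries no fold metrics (phenotype ", card$phenotype, ")",
         call. = FALSE)
  }
  list(traceability_dr = card$dynamic_range / reference$dynamic_range,
       traceability_ru = card$repression_strength / reference$repression_strength,
       unit = card$unit)
}

#' Compatibility of a pair of unit operations
#'
#' Two rules decide whether two NOT/BUFFER unit operations can be paired in
#' a combinatorial gate: (i) an extreme difference in repression units
#' (default 10-fold or greater) makes the pair incompatible -- the stronger
#' unit would nullify the weaker; (ii) if either unit has its AIU and RU in
#' proximity (raw difference below 1.5) while keeping a dynamic range of 5
#' or more, its ON state is attenuated toward super-repression and the pair
#' is flagged for caution.
#'
#' @param a,b `performance_card`s carrying fold metrics.
#' @param ru_fold_threshold Fold difference in RU deemed incompatible.
#' @param proximity_threshold Raw `|AIU - RU|` proximity bound.
#' @param dr_threshold Dynamic range required for the proximity rule.
#' @return A list of class `compatibility_report` with `ru_ratio`,
#'   `proximity_flag` and `verdict` in `{"compatible", "caution",
#'   "incompatible"}`.
#' @export
pairing_compatibility <- function(a, b, ru_fold_threshold = 10,
                                  proximity_threshold = 1.5,
                                  dr_threshold = 5) {
  stopifnot(inherits(a, "performance_card"), inherits(b, "performance_card"))
  if (!is.finite(a$dynamic_range) || !is.finite(b$dynamic_range)) {
    stop("both cards must carry fold metrics", call. = FALSE)
  }
  ru_ratio <- max(a$ru_raw, b$ru_raw) / min(a$ru_raw, b$ru_raw)
  prox <- function(card) {
    abs(card$aiu_or_iu_raw - card$ru_raw) < proximity_threshold &&
      card$dynamic_range >= dr_threshold
  }
  proximity_flag <- prox(a) || prox(b)
  verdict <- if (ru_ratio >= ru_fold_threshold) "incompatible"
             else if (proximity_flag) "caution"
             else "compatible"
  structure(list(pair = c(a$buo_id, b$buo_id), ru_ratio = ru_ratio,
                 proximity_flag = proximity_flag, verdict = verdict),
            class = "compatibility_report")
}

#' Rank unit operations against the reference
#'
#' Lists all cards whose dynamic range is greater than or equal to the
#' reference card's, ordered by dynamic range (descending, ties broken by
#' id), with per-position counts.
#'
#' @param cards A list of `performance_card`s.
#' @param reference The reference `performance_card`.
#' @return A list with `table` (data frame of qualifying cards), `count`
#'   and `count_by_position`.
#' @export
rank_vs_reference <- function(cards, reference) {
  stopifnot(length(cards) > 0L, inherits(reference, "performance_card"))
  df <- data.frame(
    buo_id = vapply(cards, `[[`, "", "buo_id"),
    position = vapply(cards, `[[`, "", "position"),
    dynamic_range = vapply(cards, function(x)
      if (is.na(x$dynamic_range)) -Inf else x$dynamic_range, 0),
    stringsAsFactors = FALSE)
  keep <- df[df$dynamic_range >= reference$dynamic_range, , drop = FALSE]
  keep <- keep[order(-keep$dynamic_range, keep$buo_id), , drop = FALSE]
  rownames(keep) <- NULL
  list(table = keep, count = nrow(keep),
       count_by_position = table(factor(keep$position,
                                        levels = c("core", "proximal"))))
}

#' Plate vs cytometry concordance
#'
#' Ordinary least-squares fit of matched plate-reader and cytometry
#' summaries for the same unit operations (one point per unit and ligand
#' state), reporting the coefficient of determination, slope and intercept.
#'
#' @param plate_values Data frame with columns `buo_id, state, value`
#'   (plate-side standardized means).
#' @param cytometry_values Data frame with columns `buo_id, state, value`
#'   (e.g. [fitc_geometric_mean()] per unit/state).
#' @return A list of class `assay_concordance` with `r_squared`, `slope`,
#'   `intercept`, `n_pairs` and the matched data.
#' @export
assay_concordance <- function(plate_values, cytometry_values) {
  needed <- c("buo_id", "state", "value")
  stopifnot(all(needed %in% names(plate_values)),
            all(needed %in% names(cytometry_values)))
  m <- merge(plate_values, cytometry_values, by = c("buo_id", "state"),
             suffixes = c("_plate", "_cyt"))
  if (nrow(m) < 3L) {
    stop("need >= 3 matched (plate, cytometry) pairs; got ", nrow(m),
         call. = FALSE)
  }
  fit <- lm(value_cyt ~ value_plate, data = m)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((m$value_cyt - mean(m$value_cyt))^2)
  structure(list(
    r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    n_pairs = nrow(m), data = m
  ), class = "assay_concordance")
}

#' @export
print.assay_concordance <- function(x, ...) {
  cat(sprintf("<assay_concordance> n = %d pairs | R^2 = %.3f | slope %.3g | intercept %.3g\n",
              x$n_pairs, x$r_squared, x$slope, x$intercept))
  invisible(x)
}

#' Serialize performance cards
#'
#' `cards_to_json()` writes one JSON object per card; `cards_table()`
#' flattens cards into a data frame suitable for CSV export.
#'
#' @param cards A list of `performance_card`s.
#' @param path Optional output path for JSON.
#' @return JSON string (or path invisibly) / a data frame.
#' @export
cards_to_json <- function(cards, path = NULL) {
  x <- lapply(cards, function(cd) {
    cd <- unclass(cd)
    cd$s_on <- as.list(cd$s_on); cd$s_off <- as.list(cd$s_off)
    cd
  })
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
  }
}

#' @rdname cards_to_json
#' @export
cards_table <- function(cards) {
  data.frame(
    buo_id = vapply(cards, `[[`, "", "buo_id"),
    phenotype = vapply(cards, `[[`, "", "phenotype"),
    position = vapply(cards, `[[`, "", "position"),
    fmo_on = vapply(cards, `[[`, 0, "fmo_on"),
    fmo_off = vapply(cards, `[[`, 0, "fmo_off"),
    dynamic_range = vapply(cards, `[[`, 0, "dynamic_range"),
    ru_raw = vapply(cards, `[[`, 0, "ru_raw"),
    floor_applied = vapply(cards, `[[`, TRUE, "floor_applied"),
    stringsAsFactors = FALSE)
}
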