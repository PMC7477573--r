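#' Blank-subtract and density-normalize a plate
#'
#' Subtracts the plate's mean blank fluorescence and mean blank OD600 from
#' every measured well, then divides fluorescence by net cell density:
#' `normalized = (fluorescence - mean blank fluorescence) /
#' (od600 - mean blank OD)`. Negative numerators are clipped to zero. Sample
#' wells whose OD does not exceed the blank OD (no detectable growth) are
#' excluded with a message.
#'
#' @param plate A `sim_plate` data frame (see [simulate_buo_plate()]) or a
#'   compatible plate CSV read with [read_plate_csv()].
#' @return The plate with a `normalized` column, blank wells removed, and
#'   attributes `blank_fluor` / `blank_od` recording the reference.
#' @export
normalize_plate <- function(plate) {
  stopifnot(is.data.frame(plate))
  blanks <- plate$sample_type == "blank"
  if (!any(blanks)) stop("plate contains no blank wells", call. = FALSE)
  bf <- mean(plate$fluorescence[blanks])
  bo <- mean(plate$od600[blanks])
  out <- plate[!blanks, , drop = FALSE]
  dead <- out$od600 <= bo
  if (any(dead)) {
    message(sum(dead), " well(s) excluded: OD600 not above blank (",
            paste(out$well[dead], collapse = ", "), ")")
    out <- out[!dead, , drop = FALSE]
  }
  num <- pmax(out$fluorescence - bf, 0)
  out$normalized <- num / (out$od600 - bo)
  attr(out, "blank_fluor") <- bf
  attr(out, "blank_od") <- bo
  class(out) <- c("sim_plate", "data.frame")
  out
}

#' Standardize normalized outputs to the stratum maximum
#'
#' Divides each well's normalized output by the mean normalized output of the
#' `lac_null` (TF-free, maximum-output) control wells of its
#' (operator, position) stratum, yielding fraction-of-maximum values. The
#' `lac_null` wells of a stratum therefore average exactly 1.
#'
#' @param plate_norm Output of [normalize_plate()].
#' @return The plate with a `standardized` column.
#' @export
standardize_to_max <- function(plate_norm) {
  stopifnot(is.data.frame(plate_norm), "normalized" %in% names(plate_norm))
  key <- paste(plate_norm$operator, plate_norm$position, sep = "|")
  is_ctrl <- plate_norm$sample_type == "lac_null"
  need <- unique(key[plate_norm$sample_type %in% c("tf", "lac_null")])
  have <- unique(key[is_ctrl])
  missing <- setdiff(need, have)
  if (length(missing)) {
    stop("no lac_null control wells for stratum (operator|position): ",
         paste(missing, collapse = "; "), call. = FALSE)
  }
  ref <- tapply(plate_norm$normalized[is_ctrl], key[is_ctrl], mean)
  plate_norm$standardized <- plate_norm$normalized / as.numeric(ref[key])
  class(plate_norm) <- c("sim_plate", "data.frame")
  plate_norm
}

#' Collect standardized replicate vectors per unit operation
#'
#' Splits a standardized plate into one record per (tf, operator, position)
#' with the replicate vectors of fraction-of-maximum output in the absence
#' (`s_no_ligand`) and presence (`s_with_ligand`) of the ligand.
#'
#' @param plate_std Output of [standardize_to_max()].
#' @return A list of `normalized_buo` objects.
#' @export
collect_buos <- function(plate_std) {
  stopifnot("standardized" %in% names(plate_std))
  tf <- plate_std[plate_std$sample_type == "tf", , drop = FALSE]
  keys <- unique(tf[, c("tf_id", "operator", "position")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- tf$tf_id == keys$tf_id[i] & tf$operator == keys$operator[i] &
      tf$position == keys$position[i]
    sub <- tf[sel, , drop = FALSE]
    no <- sub$standardized[sub$ligands == ""]
    with <- sub$standardized[sub$ligands != ""]
    if (length(no) < 2L || length(with) < 2L) {
      stop("unit operation ", keys$tf_id[i],
           " needs >= 2 replicates per ligand state", call. = FALSE)
    }
    out[[i]] <- structure(
      list(tf_id = keys$tf_id[i], operator = keys$operator[i],
           position = keys$position[i],
           s_no_ligand = no, s_with_ligand = with,
           n = min(length(no), length(with)),
           reference = "lac_null stratum mean"),
      class = "normalized_buo")
  }
  out
}

#' Welch's two-tailed t-test p-value
#'
#' Two-tailed Student's t-test allowing for unequal variances
#' (Welch-Satterthwaite), the test used to decide whether a unit operation
#' responds to its ligand. When both groups have zero variance, the p-value
#' is 1 for equal means and 0 otherwise (complete separation).
#'
#' @param a,b Replicate vectors (each of length >= 2).
#' @return The two-tailed p-value.
#' @examples
#' welch_two_tailed(c(1, 2, 3), c(1, 2, 3))  # 1
#' @export
welch_two_tailed <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (var(a) == 0 && var(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  t.test(a, b, var.equal = FALSE)$p.value
}

#' Cohen's d effect size
#'
#' Absolute mean difference divided by the pooled standard deviation.
#' A zero pooled SD with unequal means reports `Inf`.
#'
#' @param a,b Replicate vectors (each of length >= 2).
#' @return Cohen's d (non-negative; possibly `Inf`).
#' @examples
#' cohens_d(c(0, 0), c(1, 1))  # Inf (zero pooled SD)
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  diff <- abs(mean(a) - mean(b))
  if (sp2 == 0) {
    return(if (diff == 0) 0 else Inf)
  }
  diff / sqrt(sp2)
}

#' Classify a unit operation's phenotype
#'
#' Applies the study's decision rules to a standardized unit operation:
#' a significant Welch test (two-tailed, default alpha 0.001) between the
#' ligand states makes the call directional -- higher output with ligand is a
#' repressor (`X_plus`), higher output without ligand an anti-repressor
#' (`X_anti`). Without significance, the pooled mean output decides between
#' nonfunctional (`X_null`, > 50% of the stratum maximum) and
#' super-repressor (`X_super`, < 50%); a tie at exactly 50% is called
#' `X_null` (conservative).
#'
#' @param buo A `normalized_buo` (see [collect_buos()]).
#' @param alpha Significance level (default 0.001).
#' @return An object of class `phenotype_call` with fields `phenotype`,
#'   `p_value`, `cohen_d`, `mean_levels`, `significant`.
#' @export
classify_phenotype <- function(buo, alpha = 0.001) {
  stopifnot(inherits(buo, "normalized_buo"))
  p <- welch_two_tailed(buo$s_no_ligand, buo$s_with_ligand)
  d <- cohens_d(buo$s_no_ligand, buo$s_with_ligand)
  m_no <- mean(buo$s_no_ligand)
  m_with <- mean(buo$s_with_ligand)
  sig <- p < alpha
  phen <- if (sig) {
    if (m_with > m_no) "X_plus" else "X_anti"
  } else {
    if (mean(c(buo$s_no_ligand, buo$s_with_ligand)) < 0.5) "X_super"
    else "X_null"
  }
  structure(
    list(tf_id = buo$tf_id, operator = buo$operator, position = buo$position,
         phenotype = phen, p_value = p, cohen_d = d,
         mean_levels = c(no_ligand = m_no, with_ligand = m_with),
         significant = sig, alpha = alpha),
    class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(sprintf(
    "<phenotype_call> %s | %s (%s): %s (p = %.3g, d = %.2f, levels %.3f / %.3f)\n",
    x$tf_id, x$operator, x$position, x$phenotype, x$p_value, x$cohen_d,
    x$mean_levels[["no_ligand"]], x$mean_levels[["with_ligand"]]))
  invisible(x)
}

#' Classify every unit operation on a plate
#'
#' Convenience pipeline: [normalize_plate()] then [standardize_to_max()],
#' [collect_buos()] and [classify_phenotype()] on each unit operation.
#'
#' @param plate A `sim_plate` (or plate CSV data frame).
#' @param alpha Significance level.
#' @return A data frame of calls (one row per tf/operator/position) with
#'   columns `tf_id, operator, position, phenotype, p_value, cohen_d,
#'   mean_no_ligand, mean_with_ligand, significant`.
#' @export
classify_plate <- function(plate, alpha = 0.001) {
  buos <- collect_buos(standardize_to_max(normalize_plate(plate)))
  calls <- lapply(buos, classify_phenotype, alpha = alpha)
  data.frame(
    tf_id = vapply(calls, `[[`, "", "tf_id"),
    operator = vapply(calls, `[[`, "", "operator"),
    position = vapply(calls, `[[`, "", "position"),
    phenotype = vapply(calls, `[[`, "", "phenotype"),
    p_value = vapply(calls, `[[`, 0, "p_value"),
    cohen_d = vapply(calls, `[[`, 0, "cohen_d"),
    mean_no_ligand = vapply(calls, function(x) x$mean_levels[["no_ligand"]], 0),
    mean_with_ligand = vapply(calls, function(x) x$mean_levels[["with_ligand"]], 0),
    significant = vapply(calls, `[[`, TRUE, "significant"),
    stringsAsFactors = FALSE)
}

#' Assemble a DBD x operator response matrix
#'
#' Arranges phenotype calls for one regulatory core and operator position
#' into the DBD-by-operator grid, annotating each cell as cognate (the
#' operator recognized by that DBD, per the cognate map) or non-cognate, and
#' tallying significant cognate anti-repressor hits and significant
#' non-cognate interactions.
#'
#' @param calls Data frame with columns `dbd, operator, phenotype,
#'   significant` (one row per cell; e.g. [classify_plate()] output joined
#'   with TF DBDs).
#' @param cognate_map Named character vector mapping operator -> cognate DBD
#'   (see [default_cognate_map()]).
#' @return A list of class `response_matrix` with the phenotype grid, the
#'   significance grid, `cognate_anti_count` and `noncognate_significant_count`.
#' @export
build_response_matrix <- function(calls, cognate_map = default_cognate_map()) {
  needed <- c("dbd", "operator", "phenotype", "significant")
  stopifnot(all(needed %in% names(calls)))
  dbds <- sort(unique(calls$dbd))
  ops <- sort(unique(calls$operator))
  full <- expand.grid(dbd = dbds, operator = ops, stringsAsFactors = FALSE)
  key <- function(d, o) paste(d, o, sep = "|")
  have <- key(calls$dbd, calls$operator)
  missing <- setdiff(key(full$dbd, full$operator), have)
  if (length(missing)) {
    stop("incomplete response grid; missing cells (dbd|operator): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  phen <- matrix(calls$phenotype[match(key(full$dbd, full$operator), have)],
                 nrow = length(dbds), dimnames = list(dbds, ops))
  sig <- matrix(calls$significant[match(key(full$dbd, full$operator), have)],
                nrow = length(dbds), dimnames = list(dbds, ops))
  cog <- outer(dbds, ops, function(d, o) {
    mapped <- unname(cognate_map[o])
    !is.na(mapped) & mapped == d
  })
  dimnames(cog) <- list(dbds, ops)
  structure(list(
    phenotype = phen, significant = sig, cognate = cog,
    cognate_anti_count = sum(cog & phen == "X_anti" & sig),
    noncognate_significant_count = sum(!cog & sig &
                                         phen %in% c("X_anti", "X_plus"))
  ), class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix>\n")
  print(x$phenotype)
  cat(sprintf("cognate anti-repressor hits: %d | significant non-cognate: %d\n",
              x$cognate_anti_count, x$noncognate_significant_count))
  invisible(x)
}
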