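#' Cytometer model parameters
#'
#' Single-cell FITC fluorescence is log-normal around a geometric mean that
#' interpolates between the autofluorescence floor (expression level 0) and
#' the maximum-output brightness (level 1). Scatter channels are drawn from a
#' three-component mixture -- singlets, debris (sub-threshold side scatter)
#' and doublets (roughly doubled area signals) -- so that standard gating has
#' work to do.
#'
#' @param autofluor_gm Geometric-mean FITC of a non-expressing cell.
#' @param max_fitc_gm Geometric-mean FITC at maximum output.
#' @param sdlog_fitc Log-scale SD of single-cell FITC.
#' @param frac_debris,frac_doublet Mixture fractions (singlets get the rest).
#' @param ssc_threshold Acquisition side-scatter threshold; debris sits below.
#' @param doublet_ratio_cutoff Area/height ratio above which an event is
#'   discarded as a doublet.
#' @return A named list of cytometer parameters.
#' @export
cytometer_defaults <- function(autofluor_gm = 200, max_fitc_gm = 50000,
                               sdlog_fitc = 0.4, frac_debris = 0.05,
                               frac_doublet = 0.05, ssc_threshold = 5000,
                               doublet_ratio_cutoff = 1.5) {
  list(autofluor_gm = autofluor_gm, max_fitc_gm = max_fitc_gm,
       sdlog_fitc = sdlog_fitc, frac_debris = frac_debris,
       frac_doublet = frac_doublet, ssc_threshold = ssc_threshold,
       doublet_ratio_cutoff = doublet_ratio_cutoff)
}

# Draw scatter + fitc for n events at a given expression level.
draw_events <- function(n, level, condition, genotype, cyt) {
  kind <- sample(c("singlet", "debris", "doublet"), n, replace = TRUE,
                 prob = c(1 - cyt$frac_debris - cyt$frac_doublet,
                          cyt$frac_debris, cyt$frac_doublet))
  fitc_gm <- cyt$autofluor_gm + level * (cyt$max_fitc_gm - cyt$autofluor_gm)
  fitc <- rlnorm(n, log(fitc_gm), cyt$sdlog_fitc)
  fsc <- rlnorm(n, log(50000), 0.25)
  ssc <- rlnorm(n, log(20000), 0.30)
  ratio <- rlnorm(n, log(1.0), 0.05)

  deb <- kind == "debris"
  fsc[deb] <- rlnorm(sum(deb), log(8000), 0.4)
  ssc[deb] <- rlnorm(sum(deb), log(cyt$ssc_threshold * 0.4), 0.4)
  fitc[deb] <- rlnorm(sum(deb), log(cyt$autofluor_gm * 0.5), cyt$sdlog_fitc)

  dbl <- kind == "doublet"
  fsc[dbl] <- 2 * fsc[dbl]
  ssc[dbl] <- 2 * ssc[dbl]
  fitc[dbl] <- 2 * fitc[dbl]
  ratio[dbl] <- rlnorm(sum(dbl), log(1.9), 0.08)

  data.frame(
    event = seq_len(n),
    fsc_a = fsc,
    ssc_a = ssc,
    fitc_a = fitc,
    fsc_ratio = ratio,          # FSC-Area / FSC-Height
    condition = condition_label(condition),
    genotype = genotype,
    stringsAsFactors = FALSE
  )
}

as_cytometry_sample <- function(events, condition, seed = NULL) {
  events$event <- seq_len(nrow(events))
  attr(events, "condition") <- condition_label(condition)
  attr(events, "seed") <- seed
  class(events) <- c("cytometry_sample", "data.frame")
  events
}

#' Simulate single-cell cytometry for one unit operation
#'
#' FITC values are log-normally distributed with geometric mean set by the
#' profile's expression level under the given ligand condition; scatter
#' channels come from the debris/singlet/doublet mixture of
#' [cytometer_defaults()]. At least 25,000 events are recorded by default.
#'
#' @param profile An [profile_from_phenotype()] expression profile.
#' @param condition Character vector of ligands present (may be empty).
#' @param n_events Number of events (>= 1; default 25000).
#' @param seed Integer seed.
#' @param cyt Cytometer parameters, [cytometer_defaults()].
#' @return A `cytometry_sample` data frame with columns `event, fsc_a,
#'   ssc_a, fitc_a, fsc_ratio, condition, genotype`.
#' @export
simulate_cytometry <- function(profile, condition = character(0),
                               n_events = 25000L, seed = NULL,
                               cyt = cytometer_defaults()) {
  stopifnot(inherits(profile, "expression_profile"))
  if (n_events < 1L) stop("`n_events` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lev <- profile_level(profile, condition)
  ev <- draw_events(n_events, lev, condition, profile$tf_id, cyt)
  as_cytometry_sample(ev, condition, seed)
}

#' Simulate a mixed mutant library for sorting
#'
#' Draws labeled events from a genotype mixture: each genotype is an
#' expression profile with a mixture fraction, and each event's FITC
#' distribution follows its genotype's expression level under the sample's
#' ligand condition.
#'
#' @param genotype_mix A list of `list(profile = <expression_profile>,
#'   fraction = <number>)`; fractions must sum to 1 (tolerance 1e-6).
#' @param condition Ligands present during the sort.
#' @param n_events Number of events.
#' @param seed Integer seed.
#' @param cyt Cytometer parameters.
#' @return A labeled `cytometry_sample`.
#' @export
simulate_sort_library <- function(genotype_mix, condition = character(0),
                                  n_events = 50000L, seed = NULL,
                                  cyt = cytometer_defaults()) {
  fr <- vapply(genotype_mix, function(g) g$fraction, 0)
  if (abs(sum(fr) - 1) > 1e-6) {
    stop("genotype fractions must sum to 1 (got ", signif(sum(fr), 6), ")",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  labels <- vapply(genotype_mix, function(g) g$profile$tf_id, "")
  assign <- sample(seq_along(genotype_mix), n_events, replace = TRUE, prob = fr)
  pieces <- lapply(seq_along(genotype_mix), function(i) {
    n_i <- sum(assign == i)
    if (n_i == 0L) return(NULL)
    lev <- profile_level(genotype_mix[[i]]$profile, condition)
    draw_events(n_i, lev, condition, labels[i], cyt)
  })
  ev <- do.call(rbind, pieces[!vapply(pieces, is.null, TRUE)])
  ev <- ev[sample.int(nrow(ev)), , drop = FALSE]  # interleave genotypes
  as_cytometry_sample(ev, condition, seed)
}

#' Standard scatter gating
#'
#' Applies the acquisition side-scatter threshold (removing debris) and
#' doublet discrimination on the FSC area/height ratio, returning the
#' singlet events.
#'
#' @param sample A `cytometry_sample`.
#' @param cyt Cytometer parameters.
#' @return The gated `cytometry_sample`.
#' @export
gate_singlets <- function(sample, cyt = cytometer_defaults()) {
  keep <- sample$ssc_a >= cyt$ssc_threshold &
    sample$fsc_ratio <= cyt$doublet_ratio_cutoff
  out <- sample[keep, , drop = FALSE]
  class(out) <- class(sample)
  out
}

#' Geometric mean of gated FITC
#'
#' Summary statistic used when comparing cytometry with plate-reader data:
#' single-cell fluorescence is close to log-normal, so the geometric mean
#' estimates the well-level brightness.
#'
#' @param sample A `cytometry_sample`.
#' @param gated Apply [gate_singlets()] first?
#' @param cyt Cytometer parameters.
#' @return The geometric mean FITC (single number).
#' @export
fitc_geometric_mean <- function(sample, gated = TRUE,
                                cyt = cytometer_defaults()) {
  if (gated) sample <- gate_singlets(sample, cyt)
  exp(mean(log(sample$fitc_a)))
}

#' @rdname write_plate_csv
#' @param sample A `cytometry_sample`.
#' @export
write_cytometry_csv <- function(sample, path) {
  write.csv(as.data.frame(sample), path, row.names = FALSE)
  invisible(path)
}
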