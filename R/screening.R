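#' Enumerate the NNS degenerate codon set
#'
#' NNS codons (N = A/C/G/T at the first two positions, S = G/C at the third;
#' 4 x 4 x 2 = 32 codons) cover all 20 amino acids with a single stop codon
#' (TAG; TAA and TGA end in A and are excluded).
#'
#' @return A data frame with columns `codon` and `aa` (standard genetic
#'   code; `*` marks stop), with attributes `n_amino_acids` and
#'   `stop_codons`.
#' @examples
#' nrow(nns_codon_set())  # 32
#' @export
nns_codon_set <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b1 = bases, b2 = bases, b3 = c("G", "C"),
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$b1, grid$b2, grid$b3)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  out <- data.frame(codon = codons, aa = aa, stringsAsFactors = FALSE)
  attr(out, "n_amino_acids") <- length(unique(aa[aa != "*"]))
  attr(out, "stop_codons") <- codons[aa == "*"]
  out
}

#' Site-saturation library coverage
#'
#' `per_codon_coverage()` is the probability that one specific codon appears
#' at least once among `n_picks` equiprobable draws:
#' `1 - ((n_codons - 1) / n_codons)^n_picks`. For 96 picks from the 32 NNS
#' codons this is ~0.95, the usual "95% coverage" quoted for picking 96
#' colonies. `all_codons_coverage()` is the stricter coupon-collector
#' probability that every codon appears at least once, by inclusion-exclusion
#' over missed codons; it is always the smaller of the two.
#'
#' @param n_picks Number of colonies picked (>= 0).
#' @param n_codons Number of distinct codons (default 32 for NNS).
#' @return A probability.
#' @examples
#' per_codon_coverage(96)          # ~0.952
#' all_codons_coverage(96, 32)     # much lower
#' @export
per_codon_coverage <- function(n_picks, n_codons = 32L) {
  if (n_codons < 1L) stop("`n_codons` must be >= 1", call. = FALSE)
  if (n_picks < 0L) stop("`n_picks` must be >= 0", call. = FALSE)
  1 - ((n_codons - 1) / n_codons)^n_picks
}

#' @rdname per_codon_coverage
#' @export
all_codons_coverage <- function(n_picks, n_codons = 32L) {
  if (n_codons < 1L) stop("`n_codons` must be >= 1", call. = FALSE)
  if (n_picks < 0L) stop("`n_picks` must be >= 0", call. = FALSE)
  if (n_picks < n_codons) return(0)
  k <- n_codons
  j <- 0:k
  # signed log-space terms keep the alternating sum stable for k = 32
  terms <- (-1)^j * exp(lchoose(k, j) + n_picks * log1p(-j / k))
  max(min(sum(terms), 1), 0)
}

#' Picks needed to reach a coverage target
#'
#' Smallest number of picks whose coverage (per-codon or all-codon) reaches
#' the target probability; monotone in the target.
#'
#' @param target Coverage probability in (0, 1).
#' @param n_codons Number of distinct codons.
#' @param mode `"per_codon"` or `"all"`.
#' @return Integer number of picks.
#' @export
picks_for_coverage <- function(target, n_codons = 32L,
                               mode = c("per_codon", "all")) {
  mode <- match.arg(mode)
  if (!is.numeric(target) || target <= 0 || target >= 1) {
    stop("`target` must lie strictly between 0 and 1", call. = FALSE)
  }
  cov <- if (mode == "per_codon") per_codon_coverage else all_codons_coverage
  n <- if (mode == "per_codon") {
    ceiling(log(1 - target) / log((n_codons - 1) / n_codons))
  } else {
    n_codons
  }
  n <- max(n, 1L)
  while (cov(n, n_codons) < target) n <- n + 1L
  while (n > 1L && cov(n - 1L, n_codons) >= target) n <- n - 1L
  as.integer(n)
}

#' Error-prone PCR mutation statistics
#'
#' Substitution-only model: the per-clone substitution count over a mutagenized
#' region is Binomial(region length, per-base error rate). Defaults (815 bp at
#' ~0.7% error frequency) give 5-7 substitutions per clone on average,
#' touching roughly 3-5 codons.
#'
#' @param region_len Mutagenized region length in bp.
#' @param error_rate Per-base substitution probability.
#' @return A list with `mean`, `variance`, `pmf` (data frame `count`,
#'   `probability` covering all but < 1e-12 of the mass), and
#'   `expected_codons_hit` (codons with >= 1 substitution, assuming
#'   independence).
#' @export
ep_pcr_mutation_stats <- function(region_len = 815L, error_rate = 0.007) {
  if (error_rate < 0 || error_rate > 1) {
    stop("`error_rate` must lie in [0, 1]", call. = FALSE)
  }
  m <- region_len * error_rate
  v <- region_len * error_rate * (1 - error_rate)
  upper <- if (error_rate == 0) 0L else qbinom(1e-12, region_len, error_rate,
                                               lower.tail = FALSE)
  counts <- 0:upper
  pmf <- data.frame(count = counts,
                    probability = dbinom(counts, region_len, error_rate))
  n_codons <- floor(region_len / 3)
  list(mean = m, variance = v, pmf = pmf,
       expected_codons_hit = n_codons * (1 - (1 - error_rate)^3))
}

#' Anti-repressor design space
#'
#' Size of the combinatorial design space for modular TF engineering: the
#' number of engineered regulatory cores times the number of alternate
#' DNA-recognition modules each can be adapted with. The study's base space
#' is 8 engineered cores x 6 ADR modules = 48 putative anti-repressors; the
#' broader putative space (~1000 compatible cores x ~200 DBD modules)
#' exceeds 1e5.
#'
#' @param n_rcd Number of (engineered) regulatory core domains.
#' @param n_adr Number of alternate DNA-recognition modules.
#' @return The product, as a number.
#' @export
design_space_size <- function(n_rcd = 8L, n_adr = 6L) {
  stopifnot(n_rcd >= 1L, n_adr >= 1L)
  as.numeric(n_rcd) * as.numeric(n_adr)
}

#' FITC sort gate and sort plan
#'
#' A sort gate keeps events below (`collect = "low"`) or at/above
#' (`collect = "high"`) a FITC threshold (default 1e4, the bin boundary used
#' for high- vs low-fluorescence mutants). A sort plan is an ordered list of
#' steps, each a ligand condition plus a gate, applied `repeats` times (each
#' sort step is repeated once, i.e. run twice, to enrich and filter false
#' positives).
#'
#' @param threshold FITC threshold (> 0).
#' @param collect `"low"` or `"high"`.
#' @return A `sort_gate` / `sort_plan` object.
#' @export
sort_gate <- function(threshold = 1e4, collect = c("low", "high")) {
  collect <- match.arg(collect)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be > 0", call. = FALSE)
  }
  structure(list(channel = "fitc", threshold = threshold, collect = collect),
            class = "sort_gate")
}

#' @rdname sort_gate
#' @param steps List of `list(condition = <ligands>, gate = <sort_gate>,
#'   repeats = <count>)`.
#' @export
sort_plan <- function(steps) {
  stopifnot(length(steps) >= 1L)
  for (s in steps) {
    stopifnot(inherits(s$gate, "sort_gate"),
              is.null(s$repeats) || s$repeats >= 1L)
  }
  structure(list(steps = lapply(steps, function(s) {
    if (is.null(s$repeats)) s$repeats <- 1L
    s
  })), class = "sort_plan")
}

#' Two-step anti-repressor discovery sort plan
#'
#' The standard plan for enriching the anti-repressor phenotype: first sort
#' with the ligand, collecting low-fluorescence events (keeping
#' super-repressors and anti-repressors, discarding residual repressors and
#' nonfunctional clones); then sort without the ligand, collecting
#' high-fluorescence events (separating anti-repressors from
#' super-repressors). Each step runs twice.
#'
#' @param ligand The inducing ligand.
#' @param threshold FITC bin boundary.
#' @param repeats Times each step is applied (default 2).
#' @return A `sort_plan`.
#' @export
anti_repressor_sort_plan <- function(ligand, threshold = 1e4, repeats = 2L) {
  sort_plan(list(
    list(condition = ligand, gate = sort_gate(threshold, "low"),
         repeats = repeats),
    list(condition = character(0), gate = sort_gate(threshold, "high"),
         repeats = repeats)
  ))
}

#' Simulate a FACS screen over a sort plan
#'
#' Runs a labeled mutant library through a sort plan. At every application of
#' a step, a fresh sample is drawn from the current genotype composition
#' under the step's ligand condition (the sorted cells are regrown between
#' sorts), scatter-gated with [gate_singlets()], and filtered by the step's
#' FITC gate; the surviving genotype fractions are renormalized and become
#' the next composition. An empty surviving population is reported as a
#' screen failure rather than an error.
#'
#' @param genotype_mix Starting library as in [simulate_sort_library()].
#' @param plan A [sort_plan()].
#' @param n_events Events drawn per sort.
#' @param seed Integer seed.
#' @param cyt Cytometer parameters.
#' @return A list of class `sort_result`: `composition` (data frame of
#'   genotype fractions after each sort, including the starting mix),
#'   `survival` (fraction of gated events kept per sort), and `failed`.
#' @export
run_sort_plan <- function(genotype_mix, plan, n_events = 50000L, seed = NULL,
                          cyt = cytometer_defaults()) {
  stopifnot(inherits(plan, "sort_plan"))
  if (!is.null(seed)) set.seed(seed)
  labels <- vapply(genotype_mix, function(g) g$profile$tf_id, "")
  profiles <- setNames(lapply(genotype_mix, `[[`, "profile"), labels)
  fr <- setNames(vapply(genotype_mix, function(g) g$fraction, 0), labels)

  comp <- list(c(list(sort = 0L, step = 0L, pass = 0L), as.list(fr)))
  survival <- numeric(0)
  failed <- FALSE
  sort_i <- 0L

  for (step_i in seq_along(plan$steps)) {
    step <- plan$steps[[step_i]]
    for (pass in seq_len(step$repeats)) {
      sort_i <- sort_i + 1L
      mix <- lapply(labels[fr > 0], function(l) {
        list(profile = profiles[[l]], fraction = unname(fr[l]) / sum(fr))
      })
      sample <- simulate_sort_library(mix, condition = step$condition,
                                      n_events = n_events, cyt = cyt)
      gated <- gate_singlets(sample, cyt)
      keep <- if (step$gate$collect == "low") {
        gated$fitc_a < step$gate$threshold
      } else {
        gated$fitc_a >= step$gate$threshold
      }
      kept <- gated[keep, , drop = FALSE]
      survival <- c(survival, nrow(kept) / nrow(gated))
      if (nrow(kept) == 0L) {
        failed <- TRUE
        break
      }
      counts <- table(factor(kept$genotype, levels = labels))
      fr <- setNames(as.numeric(counts) / sum(counts), labels)
      comp[[length(comp) + 1L]] <-
        c(list(sort = sort_i, step = step_i, pass = pass), as.list(fr))
    }
    if (failed) break
  }
  composition <- do.call(rbind, lapply(comp, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  structure(list(composition = composition, survival = survival,
                 failed = failed),
            class = "sort_result")
}

#' @export
print.sort_result <- function(x, ...) {
  cat(sprintf("<sort_result> %d sort(s)%s\n", nrow(x$composition) - 1L,
              if (x$failed) " [FAILED: empty surviving population]" else ""))
  print(x$composition, row.names = FALSE)
  invisible(x)
}
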