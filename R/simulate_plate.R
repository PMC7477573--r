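# Mean-one multiplicative log-normal noise: E[factor] = 1 so fold changes
# estimated from arithmetic replicate means are unbiased.
ln_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# One block of wells for a sample at a given expression level and condition.
well_block <- function(plate_id, sample_type, tf_id, operator, position,
                       ligands, level, n_reps, noise) {
  od_net <- noise$od_mean * ln_factor(n_reps, noise$cv_od)
  od600 <- noise$blank_od_mean + od_net
  # Fluorescence above blank scales with expression level and with how much
  # culture grew in the well, then picks up reader noise.
  signal <- level * (noise$max_output - noise$blank_fluor_mean) *
    (od_net / noise$od_mean)
  fluor <- noise$blank_fluor_mean + signal * ln_factor(n_reps, noise$cv_fluorescence)
  data.frame(
    plate_id = plate_id,
    well = NA_character_,
    sample_type = sample_type,
    tf_id = tf_id,
    operator = operator,
    position = position,
    ligands = condition_label(ligands),
    replicate = seq_len(n_reps),
    od600 = od600,
    fluorescence = fluor,
    stringsAsFactors = FALSE
  )
}

blank_block <- function(plate_id, n_reps, noise) {
  data.frame(
    plate_id = plate_id,
    well = NA_character_,
    sample_type = "blank",
    tf_id = NA_character_,
    operator = NA_character_,
    position = NA_character_,
    ligands = "",
    replicate = seq_len(n_reps),
    od600 = noise$blank_od_mean * ln_factor(n_reps, noise$cv_od),
    fluorescence = noise$blank_fluor_mean * ln_factor(n_reps, noise$cv_fluorescence),
    stringsAsFactors = FALSE
  )
}

finish_plate <- function(wells, seed) {
  wells$well <- sprintf("W%03d", seq_len(nrow(wells)))
  attr(wells, "seed") <- seed
  class(wells) <- c("sim_plate", "data.frame")
  wells
}

#' Simulate a microwell plate assay for unit operations
#'
#' Generates a replicate-structured plate for a set of TF/operator/position
#' expression profiles, assayed with and without each profile's ligand
#' (replicates of 6 by default, as in single-TF characterization assays).
#' Every (operator, position) stratum receives `lac_null` maximum-output
#' control wells (a TF-free plasmid that defines the stratum's maximum), and
#' the plate carries media-only blank wells. Raw fluorescence is
#' `blank + level * (max_output - blank) * density_factor`, perturbed by
#' multiplicative log-normal noise on both channels.
#'
#' @param profiles A list of [profile_from_phenotype()] objects (or a single
#'   one).
#' @param noise A [noise_model()].
#' @param n_reps Biological replicates per condition (>= 2; default 6).
#' @param seed Integer seed; identical inputs and seed give an identical
#'   plate.
#' @param plate_id Plate label.
#' @return A `sim_plate` data frame with columns `plate_id, well,
#'   sample_type, tf_id, operator, position, ligands, replicate, od600,
#'   fluorescence`.
#' @examples
#' tf <- tf_spec("R_anti", "d-ribose", "HQN", "X_anti")
#' pr <- profile_from_phenotype(tf, "Ottg", "proximal")
#' plate <- simulate_buo_plate(list(pr), noise_model(), seed = 1)
#' @export
simulate_buo_plate <- function(profiles, noise = noise_model(), n_reps = 6L,
                               seed = NULL, plate_id = "plate1") {
  if (inherits(profiles, "expression_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) > 0L,
            all(vapply(profiles, inherits, TRUE, "expression_profile")),
            inherits(noise, "noise_model"))
  if (n_reps < 2L) stop("`n_reps` must be >= 2 (statistics undefined below)",
                        call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  blocks <- list()
  for (p in profiles) {
    blocks[[length(blocks) + 1L]] <- well_block(
      plate_id, "tf", p$tf_id, p$operator, p$position,
      character(0), p$level_no_ligand, n_reps, noise)
    blocks[[length(blocks) + 1L]] <- well_block(
      plate_id, "tf", p$tf_id, p$operator, p$position,
      p$ligand, p$level_with_ligand, n_reps, noise)
  }
  strata <- unique(data.frame(
    operator = vapply(profiles, `[[`, "", "operator"),
    position = vapply(profiles, `[[`, "", "position"),
    stringsAsFactors = FALSE))
  for (i in seq_len(nrow(strata))) {
    blocks[[length(blocks) + 1L]] <- well_block(
      plate_id, "lac_null", "lac_null", strata$operator[i], strata$position[i],
      character(0), 1.0, n_reps, noise)
  }
  blocks[[length(blocks) + 1L]] <- blank_block(plate_id, n_reps, noise)
  finish_plate(do.call(rbind, blocks), seed)
}

#' Simulate a logic-gate plate assay
#'
#' Generates one condition block per element of the power set of the
#' circuit's input ligands (2^k conditions for k inputs), with 12 biological
#' replicates per condition by default, as in gate assays. Well means follow
#' the circuit's quantitative composition model ([quantitative_output()]).
#' `lac_null` controls are stratified into every (operator, position) the
#' circuit uses, and blank wells are included.
#'
#' @param circuit A [circuit()].
#' @param noise A [noise_model()].
#' @param n_reps Replicates per condition (default 12).
#' @param seed Integer seed.
#' @param plate_id Plate label.
#' @param params Profile defaults used for the quantitative model.
#' @return A `sim_plate` data frame (gate wells have `sample_type = "gate"`
#'   and carry the circuit id in `tf_id`).
#' @export
simulate_gate_plate <- function(circuit, noise = noise_model(), n_reps = 12L,
                                seed = NULL, plate_id = "gate_plate",
                                params = profile_defaults()) {
  stopifnot(inherits(circuit, "buo_circuit"), inherits(noise, "noise_model"))
  if (n_reps < 2L) stop("`n_reps` must be >= 2", call. = FALSE)
  inputs <- circuit$inputs
  if (length(inputs) == 0L) {
    stop("circuit has no input ligands; nothing to assay", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  profiles <- default_circuit_profiles(circuit, params)

  blocks <- list()
  for (subset in ligand_subsets(inputs)) {
    lev <- quantitative_output(circuit, subset, profiles)
    blocks[[length(blocks) + 1L]] <- well_block(
      plate_id, "gate", circuit$id, NA_character_, NA_character_,
      subset, lev, n_reps, noise)
  }
  strata <- circuit_strata(circuit)
  for (i in seq_len(nrow(strata))) {
    blocks[[length(blocks) + 1L]] <- well_block(
      plate_id, "lac_null", "lac_null", strata$operator[i], strata$position[i],
      character(0), 1.0, n_reps, noise)
  }
  blocks[[length(blocks) + 1L]] <- blank_block(plate_id, n_reps, noise)
  finish_plate(do.call(rbind, blocks), seed)
}

# All subsets of a ligand set, empty set first, then by size.
ligand_subsets <- function(ligands) {
  ligands <- sort(unique(ligands))
  k <- length(ligands)
  out <- list(character(0))
  if (k == 0L) return(out)
  for (size in seq_len(k)) {
    combos <- utils::combn(ligands, size, simplify = FALSE)
    out <- c(out, combos)
  }
  out
}

#' Write / read plate tables as CSV
#'
#' @param plate A `sim_plate` (or compatible) data frame.
#' @param path File path.
#' @return `read_plate_csv()` returns a `sim_plate` data frame;
#'   `write_plate_csv()` returns `path` invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  write.csv(as.data.frame(plate), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("plate_id", "well", "sample_type", "tf_id", "operator",
              "position", "ligands", "replicate", "od600", "fluorescence")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("plate CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$ligands[is.na(df$ligands)] <- ""
  class(df) <- c("sim_plate", "data.frame")
  df
}
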