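#' Specify an engineered transcription factor
#'
#' A transcription factor is described by its regulatory core domain (which
#' ligand it senses), its three-residue DNA-binding-domain code (the residue
#' identities at LacI positions 17, 18 and 22, e.g. `"YQR"`), its allosteric
#' phenotype, and its expression strength (1.0 for the constitutive LacI
#' promoter; 10.0 for the stronger LacI-q promoter, which raises protein
#' production roughly ten-fold).
#'
#' @param id Character label for the TF (e.g. `"I_plus_YQR"`).
#' @param rcd_ligand Ligand sensed by the regulatory core: one of `"IPTG"`,
#'   `"fructose"`, `"d-ribose"`.
#' @param dbd Three-letter DNA-binding-domain code.
#' @param phenotype One of `"X_plus"` (repressor / BUFFER), `"X_anti"`
#'   (anti-repressor / NOT), `"X_super"` (constitutive binder), `"X_null"`
#'   (nonfunctional).
#' @param expression_strength Positive multiplier for TF production.
#' @return An object of class `tf_spec`.
#' @examples
#' tf_spec("I_plus_YQR", "IPTG", "YQR", "X_plus")
#' @export
tf_spec <- function(id, rcd_ligand, dbd, phenotype, expression_strength = 1.0) {
  stopifnot(is.character(id), length(id) == 1L)
  rcd_ligand <- match.arg(rcd_ligand, .buo_ligands)
  phenotype <- match.arg(phenotype, .buo_phenotypes)
  if (!is.character(dbd) || length(dbd) != 1L || nchar(dbd) != 3L) {
    stop("`dbd` must be a single 3-letter code (e.g. \"YQR\")", call. = FALSE)
  }
  if (!is.numeric(expression_strength) || length(expression_strength) != 1L ||
      !is.finite(expression_strength) || expression_strength <= 0) {
    stop("`expression_strength` must be a positive number", call. = FALSE)
  }
  structure(
    list(id = id, rcd_ligand = rcd_ligand, dbd = toupper(dbd),
         phenotype = phenotype,
         expression_strength = as.numeric(expression_strength)),
    class = "tf_spec"
  )
}

#' @export
print.tf_spec <- function(x, ...) {
  cat(sprintf("<tf_spec> %s: %s | DBD %s | ligand %s | expression %.1fx\n",
              x$id, x$phenotype, x$dbd, x$rcd_ligand, x$expression_strength))
  invisible(x)
}

#' Plate-reader noise model
#'
#' Measurement noise is multiplicative log-normal on both fluorescence and
#' optical density (plate-reader error scales with signal). Blank wells carry
#' media-only background. The maximum output corresponds to the brightest
#' signal observed on the instrument (75,000 r.f.u. by default), produced by
#' the TF-free `lac_null` control.
#'
#' @param cv_fluorescence Coefficient of variation of well fluorescence.
#' @param cv_od Coefficient of variation of well OD600.
#' @param blank_fluor_mean Mean fluorescence of blank (media-only) wells.
#' @param blank_od_mean Mean OD600 of blank wells.
#' @param max_output Raw fluorescence at maximum (unregulated) output.
#' @param od_mean Mean net culture density (above blank) after growth;
#'   drawn independently of genotype.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model()              # study defaults
#' noise_model(cv_fluorescence = 0, cv_od = 0)  # noise-free
#' @export
noise_model <- function(cv_fluorescence = 0.05, cv_od = 0.05,
                        blank_fluor_mean = 300, blank_od_mean = 0.04,
                        max_output = 75000, od_mean = 0.5) {
  vals <- c(cv_fluorescence, cv_od, blank_fluor_mean, blank_od_mean,
            max_output, od_mean)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all noise-model parameters must be finite and non-negative",
         call. = FALSE)
  }
  if (max_output <= blank_fluor_mean) {
    stop("`max_output` must exceed `blank_fluor_mean`", call. = FALSE)
  }
  structure(
    list(cv_fluorescence = cv_fluorescence, cv_od = cv_od,
         blank_fluor_mean = blank_fluor_mean, blank_od_mean = blank_od_mean,
         max_output = max_output, od_mean = od_mean),
    class = "noise_model"
  )
}

#' Default expression-profile parameters
#'
#' Fractions of maximum output used when mapping a phenotype onto well-level
#' expression. The unregulated ON level is 0.9; a regulated (bound) operator
#' attenuates output by the position's fold change -- larger at the core
#' position, where the bound TF competes directly with RNA polymerase, than
#' at the proximal position. Super-repressed output sits at a constitutive
#' leak, and a nonfunctional TF leaves output near maximum.
#'
#' @param on_level Unregulated ON level (fraction of maximum).
#' @param fold_proximal Dynamic range (fold change) at the proximal position.
#' @param fold_core Dynamic range at the core position (>= proximal).
#' @param leak_super Output of a constitutively bound (super-repressed) unit.
#' @param null_level Output with a nonfunctional TF.
#' @param noncognate_level Output when the TF cannot recognize the operator.
#' @return A named list of profile parameters.
#' @export
profile_defaults <- function(on_level = 0.9, fold_proximal = 10,
                             fold_core = 30, leak_super = 0.03,
                             null_level = 0.95, noncognate_level = 0.95) {
  list(on_level = on_level, fold_proximal = fold_proximal,
       fold_core = fold_core, leak_super = leak_super,
       null_level = null_level, noncognate_level = noncognate_level)
}

#' Expression profile of a TF/operator/position unit operation
#'
#' Maps a TF's phenotype onto expected expression levels (fraction of the
#' operator's maximum output) with and without its ligand, for a cognate or
#' non-cognate operator pairing at a given position. A non-cognate pairing
#' leaves the reporter essentially unregulated in both states.
#'
#' @param tf A [tf_spec()].
#' @param operator Operator label (e.g. `"O1"`, `"Ottg"`).
#' @param position `"core"` or `"proximal"`.
#' @param cognate Does the TF's DBD recognize this operator?
#' @param params Defaults table from [profile_defaults()].
#' @return An object of class `expression_profile` with fields
#'   `level_no_ligand` and `level_with_ligand` in `[0, 1]`.
#' @examples
#' tf <- tf_spec("R_anti", "d-ribose", "HQN", "X_anti")
#' profile_from_phenotype(tf, "Ottg", "proximal")
#' @export
profile_from_phenotype <- function(tf, operator, position = c("proximal", "core"),
                                   cognate = TRUE, params = profile_defaults()) {
  stopifnot(inherits(tf, "tf_spec"))
  position <- match.arg(position)
  if (!tf$phenotype %in% .buo_phenotypes) {
    stop("unknown phenotype: ", tf$phenotype, call. = FALSE)
  }
  fold <- if (position == "core") params$fold_core else params$fold_proximal
  on <- params$on_level
  leak <- on / fold
  if (!cognate) {
    lv <- c(params$noncognate_level, params$noncognate_level)
  } else {
    lv <- switch(tf$phenotype,
      X_plus = c(leak, on),                    # induced by ligand
      X_anti = c(on, leak),                    # silenced by ligand
      X_super = c(params$leak_super, params$leak_super),
      X_null = c(params$null_level, params$null_level)
    )
  }
  structure(
    list(tf_id = tf$id, ligand = tf$rcd_ligand, dbd = tf$dbd,
         phenotype = tf$phenotype, operator = operator, position = position,
         cognate = cognate,
         level_no_ligand = lv[[1L]], level_with_ligand = lv[[2L]]),
    class = "expression_profile"
  )
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf(
    "<expression_profile> %s | %s (%s): level %.3f (no ligand), %.3f (+%s)\n",
    x$tf_id, x$operator, x$position, x$level_no_ligand, x$level_with_ligand,
    x$ligand))
  invisible(x)
}

# Expression level of a profile under a ligand condition (character vector
# of ligands present).
profile_level <- function(profile, ligands) {
  if (profile$ligand %in% ligands) profile$level_with_ligand
  else profile$level_no_ligand
}

# Canonical condition label: ligands sorted and semicolon-joined ("" = none).
condition_label <- function(ligands) {
  if (length(ligands) == 0L) "" else paste(sort(ligands), collapse = ";")
}

condition_ligands <- function(label) {
  if (is.na(label) || !nzchar(label)) character(0)
  else strsplit(label, ";", fixed = TRUE)[[1L]]
}
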