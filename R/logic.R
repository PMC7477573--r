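#' Default operator -> cognate DBD map
#'
#' Each engineered operator is recognized by exactly one three-residue DBD
#' code. `O1` and its symmetrized, higher-affinity variant `Osym` are both
#' recognized by the wild-type YQR domain.
#'
#' @return Named character vector mapping operator label to DBD code.
#' @export
default_cognate_map <- function() {
  c(O1 = "YQR", Osym = "YQR", Ottg = "HQN", Oagg = "KSL", Ogta = "NAR")
}

#' Operator node and channel constructors
#'
#' An `operator_node` is an operator at a position (`core` or `proximal`); a
#' `channel` is a promoter with up to one node per position driving one
#' output gene. A circuit has one or two channels (two channels in the
#' parallel architecture must share the output gene so their outputs couple).
#'
#' @param operator Operator label.
#' @param position `"core"` or `"proximal"`.
#' @return An `operator_node`.
#' @export
operator_node <- function(operator, position = c("proximal", "core")) {
  position <- match.arg(position)
  structure(list(operator = operator, position = position),
            class = "operator_node")
}

#' @rdname operator_node
#' @param promoter Promoter scaffold label (`"trc"`, `"pL"`, `"pL_mut"`).
#' @param nodes List of `operator_node`s (at most one per position).
#' @param output_gene Output gene label.
#' @return A `channel`.
#' @export
channel <- function(promoter = "trc", nodes, output_gene = "sfGFP") {
  if (inherits(nodes, "operator_node")) nodes <- list(nodes)
  stopifnot(length(nodes) >= 0L,
            all(vapply(nodes, inherits, TRUE, "operator_node")))
  pos <- vapply(nodes, `[[`, "", "position")
  if (anyDuplicated(pos)) {
    stop("a channel may carry at most one core and one proximal node",
         call. = FALSE)
  }
  structure(list(promoter = promoter, nodes = nodes,
                 output_gene = output_gene),
            class = "buo_channel")
}

#' Define a genetic logic circuit
#'
#' A circuit is a set of transcription factors plus one or two channels of
#' operator nodes, with a cognate map (which DBD recognizes which operator)
#' and an effectiveness rule for core-position competition with RNA
#' polymerase. By default every cognate interaction is effective except a
#' wild-type-affinity repressor (`X_plus`, YQR) facing `O1` at the core at
#' baseline expression: there RNA polymerase outcompetes the TF and the
#' interaction is nullified. Raising the operator affinity (`Osym`) or the
#' TF's expression (strength >= 10) restores effectiveness. Overrides can
#' force any (tf, operator, position) entry.
#'
#' @param channels List of [channel()]s (1 or 2; two channels must share the
#'   output gene).
#' @param tfs List of [tf_spec()]s.
#' @param cognate_map Operator -> DBD map ([default_cognate_map()]).
#' @param effectiveness_overrides Optional data frame with columns
#'   `tf_id, operator, position, effective`.
#' @param inputs Input ligands; defaults to the ligands of the circuit's
#'   ligand-responsive TFs (`X_plus`/`X_anti`).
#' @param id Circuit label.
#' @return An object of class `buo_circuit`.
#' @export
circuit <- function(channels, tfs, cognate_map = default_cognate_map(),
                    effectiveness_overrides = NULL, inputs = NULL,
                    id = "circuit") {
  if (inherits(channels, "buo_channel")) channels <- list(channels)
  if (inherits(tfs, "tf_spec")) tfs <- list(tfs)
  stopifnot(length(channels) %in% 1:2,
            all(vapply(channels, inherits, TRUE, "buo_channel")),
            length(tfs) >= 1L,
            all(vapply(tfs, inherits, TRUE, "tf_spec")))
  if (length(channels) == 2L &&
      channels[[1L]]$output_gene != channels[[2L]]$output_gene) {
    stop("parallel channels must share the output gene", call. = FALSE)
  }
  if (is.null(inputs)) {
    responsive <- vapply(tfs, `[[`, "", "phenotype") %in% c("X_plus", "X_anti")
    inputs <- sort(unique(vapply(tfs[responsive], `[[`, "", "rcd_ligand")))
  }
  if (!is.null(effectiveness_overrides)) {
    stopifnot(all(c("tf_id", "operator", "position", "effective") %in%
                    names(effectiveness_overrides)))
  }
  structure(list(id = id, channels = channels, tfs = tfs,
                 cognate_map = cognate_map,
                 effectiveness_overrides = effectiveness_overrides,
                 inputs = inputs),
            class = "buo_circuit")
}

#' @export
print.buo_circuit <- function(x, ...) {
  cat(sprintf("<circuit> %s: %d channel(s), %d TF(s), inputs {%s}\n",
              x$id, length(x$channels), length(x$tfs),
              paste(x$inputs, collapse = ", ")))
  invisible(x)
}

circuit_strata <- function(circuit) {
  nodes <- unlist(lapply(circuit$channels, `[[`, "nodes"), recursive = FALSE)
  unique(data.frame(
    operator = vapply(nodes, `[[`, "", "operator"),
    position = vapply(nodes, `[[`, "", "position"),
    stringsAsFactors = FALSE))
}

#' Does a TF bind DNA under a ligand condition?
#'
#' Phenotype truth semantics: a repressor (`X_plus`) binds until induced
#' (binds iff its ligand is absent); an anti-repressor (`X_anti`) binds only
#' when its ligand is present; a super-repressor always binds; a
#' nonfunctional TF never binds.
#'
#' @param tf A [tf_spec()].
#' @param ligands Character vector of ligands present.
#' @return Logical.
#' @export
binds <- function(tf, ligands) {
  stopifnot(inherits(tf, "tf_spec"))
  switch(tf$phenotype,
    X_plus = !(tf$rcd_ligand %in% ligands),
    X_anti = tf$rcd_ligand %in% ligands,
    X_super = TRUE,
    X_null = FALSE)
}

# Is this TF able to exert regulation at (operator, position)? Core-position
# competition with RNA polymerase is encoded as a per-entry effectiveness
# flag rather than a thermodynamic occupancy model.
tf_effective <- function(tf, operator, position, circuit) {
  ov <- circuit$effectiveness_overrides
  if (!is.null(ov)) {
    hit <- ov$tf_id == tf$id & ov$operator == operator & ov$position == position
    if (any(hit)) return(ov$effective[which(hit)[1L]])
  }
  # The wild-type-affinity LacI-core repressor is outcompeted by RNA
  # polymerase at the O1 core position at baseline expression; raising
  # operator affinity (Osym) or expression (>= 10x) restores function.
  if (position == "core" && operator == "O1" && tf$phenotype == "X_plus" &&
      tf$dbd == "YQR" && tf$rcd_ligand == "IPTG" &&
      tf$expression_strength < 10) {
    return(FALSE)
  }
  TRUE
}

cognate_tfs <- function(node, circuit) {
  target <- unname(circuit$cognate_map[node$operator])
  if (is.na(target)) return(list())
  Filter(function(tf) {
    tf$dbd == target && tf_effective(tf, node$operator, node$position, circuit)
  }, circuit$tfs)
}

#' Is an operator node occupied under a ligand condition?
#'
#' A node is occupied iff any TF whose DBD is cognate to the node's operator
#' both binds under the condition ([binds()]) and is effective at that
#' (operator, position). Multiple TFs sharing a DBD exchange independently on
#' the single operator (the series-parallel mechanism), so any one binding
#' suffices.
#'
#' @param node An [operator_node()] belonging to the circuit.
#' @param circuit A [circuit()].
#' @param ligands Ligands present.
#' @return Logical.
#' @export
operator_occupied <- function(node, circuit, ligands) {
  stopifnot(inherits(node, "operator_node"), inherits(circuit, "buo_circuit"))
  any(vapply(cognate_tfs(node, circuit), binds, TRUE, ligands = ligands))
}

#' Is transcription permitted through a channel?
#'
#' A channel transmits iff every one of its nodes is unoccupied (series
#' conjunction along the DNA); a channel with no nodes is constitutive.
#'
#' @param chan A [channel()] of the circuit.
#' @inheritParams operator_occupied
#' @return Logical.
#' @export
channel_permitted <- function(chan, circuit, ligands) {
  stopifnot(inherits(chan, "buo_channel"))
  !any(vapply(chan$nodes, operator_occupied, TRUE,
              circuit = circuit, ligands = ligands))
}

#' Boolean circuit output under a ligand condition
#'
#' The coupled output is high iff any channel permits transcription
#' (parallel disjunction across channels).
#'
#' @inheritParams operator_occupied
#' @return Logical.
#' @export
circuit_output <- function(circuit, ligands) {
  stopifnot(inherits(circuit, "buo_circuit"))
  any(vapply(circuit$channels, channel_permitted, TRUE,
             circuit = circuit, ligands = ligands))
}

# Default per-node expression profiles for a circuit's quantitative model.
default_circuit_profiles <- function(circuit, params = profile_defaults()) {
  out <- list()
  for (chan in circuit$channels) {
    for (node in chan$nodes) {
      for (tf in cognate_tfs(node, circuit)) {
        keyed <- profile_from_phenotype(tf, node$operator, node$position,
                                        cognate = TRUE, params = params)
        out[[paste(tf$id, node$operator, node$position, sep = "|")]] <- keyed
      }
    }
  }
  out
}

#' Quantitative circuit output
#'
#' Deterministic fraction-of-maximum output: each node transmits the minimum
#' expression level (under the condition) across its cognate effective TFs'
#' profiles -- i.e. the leak of the tightest bound TF when occupied, and the
#' ON level when free; a channel multiplies its node transmissions; the
#' coupled output is the maximum across channels (the gate normalization
#' anchors the ON plateau at 1, which max reproduces).
#'
#' @param circuit A [circuit()].
#' @param ligands Ligands present.
#' @param profiles Named list of expression profiles keyed
#'   `"tf|operator|position"` (see [profile_from_phenotype()]); defaults are
#'   derived from the circuit's TFs.
#' @param params Profile defaults for nodes with no cognate TF.
#' @return A number in `[0, 1]`.
#' @export
quantitative_output <- function(circuit, ligands,
                                profiles = default_circuit_profiles(circuit),
                                params = profile_defaults()) {
  stopifnot(inherits(circuit, "buo_circuit"))
  chan_level <- vapply(circuit$channels, function(chan) {
    trans <- vapply(chan$nodes, function(node) {
      tfs <- cognate_tfs(node, circuit)
      if (length(tfs) == 0L) return(params$on_level)
      levs <- vapply(tfs, function(tf) {
        key <- paste(tf$id, node$operator, node$position, sep = "|")
        pr <- profiles[[key]]
        if (is.null(pr)) {
          stop("missing expression profile for ", key, call. = FALSE)
        }
        profile_level(pr, ligands)
      }, 0)
      min(levs)
    }, 0)
    prod(trans)
  }, 0)
  max(chan_level)
}

#' Predict a circuit's truth table
#'
#' Enumerates all 2^k subsets of the circuit's k input ligands and records
#' the Boolean output ([circuit_output()]) and the quantitative output
#' ([quantitative_output()]) for each.
#'
#' @param circuit A [circuit()] with 1-4 input ligands.
#' @param params Profile defaults for the quantitative model.
#' @return A `truth_table` data frame: one logical presence column per
#'   ligand plus `condition`, `output` (logical) and `level` (numeric).
#' @export
predict_truth_table <- function(circuit, params = profile_defaults()) {
  stopifnot(inherits(circuit, "buo_circuit"))
  inputs <- circuit$inputs
  if (length(inputs) < 1L) {
    stop("circuit has no input ligands", call. = FALSE)
  }
  if (length(inputs) > 4L) {
    stop("truth tables supported for up to 4 input ligands", call. = FALSE)
  }
  profiles <- default_circuit_profiles(circuit, params)
  subsets <- ligand_subsets(inputs)
  pres <- as.data.frame(
    do.call(rbind, lapply(subsets, function(s) inputs %in% s)))
  names(pres) <- inputs
  pres$condition <- vapply(subsets, condition_label, "")
  pres$output <- vapply(subsets, function(s) circuit_output(circuit, s), TRUE)
  pres$level <- vapply(subsets, function(s)
    quantitative_output(circuit, s, profiles, params), 0)
  structure(pres, inputs = inputs, class = c("truth_table", "data.frame"))
}

#' Name a truth table's logic gate
#'
#' Matches a truth table against canonical gate patterns: constants, BUFFER
#' and NOT (one input), AND, OR, NOR, NAND, XOR, XNOR (two or more inputs
#' where defined), and single-input reductions (a multi-input table whose
#' output depends on one ligand only is reported as e.g.
#' `"single-input (d-ribose BUFFER)"`). Anything else is `"unclassified"`.
#'
#' @param table A `truth_table` ([predict_truth_table()]) or a data frame
#'   with logical input columns and a logical `output` column.
#' @return The gate name (character).
#' @export
classify_gate <- function(table) {
  inputs <- attr(table, "inputs")
  if (is.null(inputs)) {
    inputs <- setdiff(names(table), c("condition", "output", "level"))
  }
  k <- length(inputs)
  stopifnot(k >= 1L, "output" %in% names(table))
  out <- table$output
  if (anyNA(out)) return("unclassified")
  out <- unname(out)
  pres <- as.matrix(table[, inputs, drop = FALSE])
  dimnames(pres) <- list(NULL, inputs)
  n_on <- unname(rowSums(pres))

  if (all(out)) return("constant 1")
  if (!any(out)) return("constant 0")
  if (k == 1L) {
    return(if (identical(out, as.logical(pres[, 1L]))) "BUFFER" else "NOT")
  }
  if (identical(out, n_on == k)) return("AND")
  if (identical(out, n_on > 0)) return("OR")
  if (identical(out, n_on == 0)) return("NOR")
  if (identical(out, n_on < k)) return("NAND")
  if (k == 2L && identical(out, n_on %% 2 == 1)) return("XOR")
  if (k == 2L && identical(out, n_on %% 2 == 0)) return("XNOR")
  for (lig in inputs) {
    p <- as.logical(pres[, lig])
    if (identical(out, p)) return(sprintf("single-input (%s BUFFER)", lig))
    if (identical(out, !p)) return(sprintf("single-input (%s NOT)", lig))
  }
  "unclassified"
}

#' Read / write circuits as JSON
#'
#' Circuit JSON schema: `inputs`, `tfs` (id, rcd_ligand, dbd, phenotype,
#' expression_strength), `channels` (promoter, nodes of operator/position,
#' output_gene), `cognate_map`, and optional `effectiveness_overrides`.
#'
#' @param circuit A [circuit()].
#' @param path File path (for `circuit_to_json`, `NULL` returns the string).
#' @return `circuit_from_json()` returns a `buo_circuit`.
#' @export
circuit_to_json <- function(circuit, path = NULL) {
  x <- list(
    id = circuit$id,
    inputs = circuit$inputs,
    tfs = lapply(circuit$tfs, unclass),
    channels = lapply(circuit$channels, function(ch) {
      list(promoter = ch$promoter,
           nodes = lapply(ch$nodes, unclass),
           output_gene = ch$output_gene)
    }),
    cognate_map = as.list(circuit$cognate_map),
    effectiveness_overrides = circuit$effectiveness_overrides
  )
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, null = "null")
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null")
    invisible(path)
  }
}

#' @rdname circuit_to_json
#' @param json A JSON string or file path.
#' @export
circuit_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  tfs <- lapply(x$tfs, function(tf) {
    tf_spec(tf$id, tf$rcd_ligand, tf$dbd, tf$phenotype,
            if (is.null(tf$expression_strength)) 1.0 else tf$expression_strength)
  })
  chans <- lapply(x$channels, function(ch) {
    nodes <- lapply(ch$nodes, function(nd) operator_node(nd$operator, nd$position))
    channel(ch$promoter, nodes, ch$output_gene)
  })
  ov <- NULL
  if (!is.null(x$effectiveness_overrides)) {
    ov <- do.call(rbind, lapply(x$effectiveness_overrides, as.data.frame))
  }
  circuit(chans, tfs,
          cognate_map = unlist(x$cognate_map),
          effectiveness_overrides = ov,
          inputs = if (is.null(x$inputs)) NULL else unlist(x$inputs),
          id = if (is.null(x$id)) "circuit" else x$id)
}
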