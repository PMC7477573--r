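# Placeholder part sequences. Operator sequences for the engineered
# alternate-recognition operators are not public; symbolic IDs are
# authoritative and sequences are config-supplied, validated by length only.
# Insulator/gene/terminator placeholders carry correct labels and realistic
# lengths; real part sequences can be supplied via `parts`.
default_parts <- function() {
  list(
    spacer17 = "ACTGGCACGTATTGTGC",                  # neutral 17-bp inter-hexamer spacer
    insulator_RiboJ = paste(rep("AGCTGTCACCGGATGTGC", 2), collapse = ""),
    insulator_RiboJ10 = paste(rep("AGTTGTCACCGGTTGTAC", 2), collapse = ""),
    gene_sfGFP = paste(rep("ATGGTGAGCAAGGGCGAGGA", 3), collapse = ""),
    terminator_rrnb1 = "CAAATAAAACGAAAGGCTCAGTCGAAAGACTGGGCC"
  )
}

#' Promoter scaffolds
#'
#' The three promoter scaffolds used in the cassette builders. All share the
#' -35 hexamer `TTGACA`; the -10 hexamer is `TATAAT` for the trc scaffold,
#' `GATACT` for the strong pL scaffold, and `GACTAT` for the weakened pL
#' variant used to balance OFF states between channels.
#'
#' @param name One of `"trc"`, `"pL"`, `"pL_mut"`.
#' @return An object of class `promoter_scaffold` with fields `name`,
#'   `minus35`, `minus10`.
#' @examples
#' promoter_scaffold("trc")
#' @export
promoter_scaffold <- function(name = c("trc", "pL", "pL_mut")) {
  name <- match.arg(name)
  minus10 <- switch(name, trc = "TATAAT", pL = "GATACT", pL_mut = "GACTAT")
  structure(list(name = name, minus35 = "TTGACA", minus10 = minus10),
            class = "promoter_scaffold")
}

check_dna <- function(x, what) {
  if (!is.character(x) || length(x) != 1L ||
      !grepl("^[ACGTacgt]+$", x)) {
    stop(what, " must be a DNA string (A/C/G/T)", call. = FALSE)
  }
  toupper(x)
}

# Assemble a record from an ordered list of (label, seq) parts.
# Coordinates are 0-based half-open.
assemble_record <- function(parts_list, name) {
  seqs <- vapply(parts_list, `[[`, "", "seq")
  labels <- vapply(parts_list, `[[`, "", "label")
  ends <- cumsum(nchar(seqs))
  starts <- c(0L, ends[-length(ends)])
  feat <- data.frame(label = labels, start = as.integer(starts),
                     end = as.integer(ends), stringsAsFactors = FALSE)
  feat <- feat[!grepl("^_", feat$label), , drop = FALSE]  # "_" = unannotated
  rownames(feat) <- NULL
  structure(list(name = name, sequence = paste(seqs, collapse = ""),
                 features = feat),
            class = "cassette_record")
}

#' @export
print.cassette_record <- function(x, ...) {
  cat(sprintf("<cassette_record> %s (%d bp, %d features)\n",
              x$name, nchar(x$sequence), nrow(x$features)))
  print(x$features, row.names = FALSE)
  invisible(x)
}

part <- function(label, seq) list(label = label, seq = seq)

downstream_parts <- function(parts, insulator = "RiboJ", gene = "sfGFP",
                             terminator = TRUE) {
  out <- list(
    part(paste0("insulator_", insulator),
         parts[[paste0("insulator_", insulator)]]),
    part(paste0("gene_", gene), parts$gene_sfGFP)
  )
  if (terminator) {
    out <- c(out, list(part("terminator_rrnb1", parts$terminator_rrnb1)))
  }
  out
}

#' Build a core-position reporter cassette
#'
#' Places a 17-bp operator in the region between the -35 and -10 hexamers of
#' the promoter, so a bound TF competes directly with RNA polymerase.
#'
#' @param scaffold A [promoter_scaffold()].
#' @param operator_seq 17-bp operator DNA string.
#' @param operator_label Feature label for the operator.
#' @param parts Named list of part sequences ([default_parts()]).
#' @param insulator Insulator label (`"RiboJ"` or `"RiboJ10"`).
#' @param terminator Append the terminator feature?
#' @return A `cassette_record` whose features place `minus35`, the operator,
#'   and `minus10` contiguously.
#' @examples
#' rec <- build_core_promoter(promoter_scaffold("trc"), "AATTGTGAGCGGATAAC")
#' validate_layout(rec)
#' @export
build_core_promoter <- function(scaffold, operator_seq,
                                operator_label = "operator_core",
                                parts = default_parts(),
                                insulator = "RiboJ", terminator = TRUE) {
  stopifnot(inherits(scaffold, "promoter_scaffold"))
  operator_seq <- check_dna(operator_seq, "`operator_seq`")
  if (nchar(operator_seq) != 17L) {
    stop("core operator must be exactly 17 bp (got ", nchar(operator_seq),
         " bp): the operator replaces the inter-hexamer spacer", call. = FALSE)
  }
  assemble_record(c(list(
    part("minus35", scaffold$minus35),
    part(operator_label, operator_seq),
    part("minus10", scaffold$minus10)
  ), downstream_parts(parts, insulator, terminator = terminator)),
  name = paste0(scaffold$name, "_core"))
}

#' Build a proximal-position reporter cassette
#'
#' Places the operator downstream of the -10 hexamer (default offset 15 bp),
#' where TF and RNA polymerase bind without direct competition. The promoter
#' keeps a neutral 17-bp inter-hexamer spacer.
#'
#' @inheritParams build_core_promoter
#' @param operator_seq Operator DNA string (any length >= 1).
#' @param spacer_len Bases between the end of the -10 box and the operator.
#' @return A `cassette_record`.
#' @export
build_proximal_cassette <- function(scaffold, operator_seq, spacer_len = 15L,
                                    operator_label = "operator_proximal",
                                    parts = default_parts(),
                                    insulator = "RiboJ", terminator = TRUE) {
  stopifnot(inherits(scaffold, "promoter_scaffold"))
  operator_seq <- check_dna(operator_seq, "`operator_seq`")
  if (spacer_len < 0L) stop("`spacer_len` must be >= 0", call. = FALSE)
  spacer <- if (spacer_len > 0L) {
    substr(strrep("TCGAC", ceiling(spacer_len / 5)), 1L, spacer_len)
  } else ""
  pl <- list(
    part("minus35", scaffold$minus35),
    part("_spacer_interhex", parts$spacer17),
    part("minus10", scaffold$minus10)
  )
  if (nzchar(spacer)) pl <- c(pl, list(part("_spacer_proximal", spacer)))
  pl <- c(pl, list(part(operator_label, operator_seq)),
          downstream_parts(parts, insulator, terminator = terminator))
  assemble_record(pl, name = paste0(scaffold$name, "_proximal"))
}

#' Build a series (SERI) cassette: core + proximal operators on one gene
#'
#' One operator is intercalated between the hexamers (core) and a second sits
#' 15 bp downstream of the -10 box (proximal), both upstream of a single
#' insulated reporter gene, so two TFs regulate one output in series.
#'
#' @inheritParams build_core_promoter
#' @param core_operator 17-bp core operator sequence.
#' @param proximal_operator Proximal operator sequence.
#' @param spacer_len Offset of the proximal operator from the -10 box.
#' @return A `cassette_record` with both operator features.
#' @export
build_series_cassette <- function(core_operator, proximal_operator,
                                  scaffold = promoter_scaffold("trc"),
                                  spacer_len = 15L,
                                  parts = default_parts(),
                                  insulator = "RiboJ", terminator = TRUE) {
  stopifnot(inherits(scaffold, "promoter_scaffold"))
  core_operator <- check_dna(core_operator, "`core_operator`")
  proximal_operator <- check_dna(proximal_operator, "`proximal_operator`")
  if (nchar(core_operator) != 17L) {
    stop("core operator must be exactly 17 bp (got ", nchar(core_operator),
         " bp)", call. = FALSE)
  }
  if (spacer_len < 0L) stop("`spacer_len` must be >= 0", call. = FALSE)
  spacer <- if (spacer_len > 0L) {
    substr(strrep("TCGAC", ceiling(spacer_len / 5)), 1L, spacer_len)
  } else ""
  pl <- list(
    part("minus35", scaffold$minus35),
    part("operator_core", core_operator),
    part("minus10", scaffold$minus10)
  )
  if (nzchar(spacer)) pl <- c(pl, list(part("_spacer_proximal", spacer)))
  pl <- c(pl, list(part("operator_proximal", proximal_operator)),
          downstream_parts(parts, insulator, terminator = terminator))
  assemble_record(pl, name = paste0(scaffold$name, "_series"))
}

#' Build a parallel (PARA) record: two channels, one output
#'
#' Concatenates two single-channel cassettes into a two-channel record. The
#' channels must carry distinct ribozyme insulators (RiboJ vs RiboJ10, to
#' avoid repeated sequence), each has its own gene copy, and a terminator
#' follows channel 1.
#'
#' @param channel1,channel2 `cassette_record`s built with distinct
#'   `insulator` labels (channel 1 must end in a terminator).
#' @return A combined `cassette_record`; channel-2 features are suffixed
#'   `".ch2"`.
#' @export
build_parallel_record <- function(channel1, channel2) {
  stopifnot(inherits(channel1, "cassette_record"),
            inherits(channel2, "cassette_record"))
  ins1 <- grep("^insulator_", channel1$features$label, value = TRUE)
  ins2 <- grep("^insulator_", channel2$features$label, value = TRUE)
  if (length(ins1) != 1L || length(ins2) != 1L) {
    stop("each channel must carry exactly one insulator feature", call. = FALSE)
  }
  if (ins1 == ins2) {
    stop("channels share the insulator ", ins1,
         "; use distinct insulators (RiboJ vs RiboJ10)", call. = FALSE)
  }
  if (!"terminator_rrnb1" %in% channel1$features$label) {
    stop("channel 1 must end in a terminator", call. = FALSE)
  }
  off <- nchar(channel1$sequence)
  f2 <- channel2$features
  f2$start <- f2$start + off
  f2$end <- f2$end + off
  f2$label <- paste0(f2$label, ".ch2")
  structure(list(
    name = paste0(channel1$name, "+", channel2$name),
    sequence = paste0(channel1$sequence, channel2$sequence),
    features = rbind(channel1$features, f2)
  ), class = "cassette_record")
}

#' Validate a cassette layout
#'
#' Locates the annotated -35/-10 hexamers, measures the inter-hexamer
#' spacing and any proximal-operator offset, lists insulators, and flags
#' violations of the layout rules (17-bp core spacing; feature bounds;
#' overlapping operators). Violations are reported, not raised.
#'
#' @param record A `cassette_record`.
#' @return A list of class `layout_report` with elements `minus35`,
#'   `minus10`, `core_spacing`, `proximal_offset`, `insulators`,
#'   `violations` (character vector), and per-channel detail for parallel
#'   records.
#' @export
validate_layout <- function(record) {
  stopifnot(inherits(record, "cassette_record"))
  f <- record$features
  viol <- character(0)
  n <- nchar(record$sequence)
  bad <- f$start < 0 | f$end > n | f$end < f$start
  if (any(bad)) {
    viol <- c(viol, paste0("feature out of bounds: ",
                           paste(f$label[bad], collapse = ", ")))
  }
  ops <- f[grepl("^operator", f$label), , drop = FALSE]
  if (nrow(ops) > 1L) {
    o <- ops[order(ops$start), ]
    if (any(o$start[-1L] < o$end[-nrow(o)])) {
      viol <- c(viol, "overlapping operator features")
    }
  }

  channel_report <- function(fc) {
    m35 <- fc[fc$label == "minus35", , drop = FALSE]
    m10 <- fc[fc$label == "minus10", , drop = FALSE]
    rep <- list(minus35 = NA_character_, minus10 = NA_character_,
                core_spacing = NA_integer_, proximal_offset = NA_integer_,
                violations = character(0))
    if (nrow(m35) == 1L) {
      rep$minus35 <- substr(record$sequence, m35$start + 1L, m35$end)
    } else rep$violations <- c(rep$violations, "minus35 hexamer not found")
    if (nrow(m10) == 1L) {
      rep$minus10 <- substr(record$sequence, m10$start + 1L, m10$end)
    } else rep$violations <- c(rep$violations, "minus10 hexamer not found")
    if (nrow(m35) == 1L && nrow(m10) == 1L) {
      rep$core_spacing <- m10$start - m35$end
      if (rep$core_spacing != 17L) {
        rep$violations <- c(rep$violations, sprintf(
          "inter-hexamer spacing is %d bp (expected 17)", rep$core_spacing))
      }
      core <- fc[fc$label == "operator_core", , drop = FALSE]
      if (nrow(core) == 1L &&
          (core$start != m35$end || core$end != m10$start)) {
        rep$violations <- c(rep$violations,
                            "core operator not contiguous with hexamers")
      }
      prox <- fc[fc$label == "operator_proximal", , drop = FALSE]
      if (nrow(prox) == 1L) rep$proximal_offset <- prox$start - m10$end
    }
    rep
  }

  is_ch2 <- grepl("\\.ch2$", f$label)
  if (any(is_ch2)) {
    f1 <- f[!is_ch2, , drop = FALSE]
    f2 <- f[is_ch2, , drop = FALSE]
    f2$label <- sub("\\.ch2$", "", f2$label)
    r1 <- channel_report(f1)
    r2 <- channel_report(f2)
    ch2_viol <- if (length(r2$violations)) paste0("ch2: ", r2$violations)
                else character(0)
    viol <- c(viol, r1$violations, ch2_viol)
    rep <- list(minus35 = r1$minus35, minus10 = r1$minus10,
                core_spacing = r1$core_spacing,
                proximal_offset = r1$proximal_offset,
                channels = list(r1, r2))
  } else {
    r1 <- channel_report(f)
    viol <- c(viol, r1$violations)
    rep <- r1
    rep$violations <- NULL
  }
  rep$insulators <- sub("^insulator_", "",
                        grep("^insulator_", sub("\\.ch2$", "", f$label),
                             value = TRUE))
  rep$violations <- viol
  class(rep) <- "layout_report"
  rep
}

#' @export
print.layout_report <- function(x, ...) {
  cat(sprintf("<layout_report> -35 %s | -10 %s | core spacing %s bp | proximal offset %s bp\n",
              x$minus35, x$minus10, x$core_spacing, x$proximal_offset))
  cat("insulators:", paste(x$insulators, collapse = ", "), "\n")
  if (length(x$violations)) {
    cat("violations:\n"); for (v in x$violations) cat(" -", v, "\n")
  } else cat("no violations\n")
  invisible(x)
}

#' Export a cassette record
#'
#' `write_cassette_fasta()` writes the sequence as FASTA;
#' `write_cassette_genbank()` writes a minimal GenBank flat file with the
#' feature annotations (1-based inclusive coordinates, per the format);
#' `layout_report_json()` serializes a [validate_layout()] report.
#'
#' @param record A `cassette_record`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cassette_fasta <- function(record, path) {
  x <- Biostrings::DNAStringSet(record$sequence)
  names(x) <- record$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_cassette_fasta
#' @export
write_cassette_genbank <- function(record, path) {
  n <- nchar(record$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN",
                     substr(record$name, 1, 16), n), con)
  writeLines(sprintf("DEFINITION  %s synthetic reporter cassette.",
                     record$name), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (i in seq_len(nrow(record$features))) {
    ft <- record$features[i, ]
    writeLines(sprintf("     misc_feature    %d..%d", ft$start + 1L, ft$end),
               con)
    writeLines(sprintf("                     /label=\"%s\"", ft$label), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$sequence)
  for (start in seq(1L, n, by = 60L)) {
    chunk <- substr(s, start, min(start + 59L, n))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", start, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' @rdname write_cassette_fasta
#' @param report A `layout_report`.
#' @export
layout_report_json <- function(report, path = NULL) {
  x <- unclass(report)
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, null = "null")
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null")
    invisible(path)
  }
}
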