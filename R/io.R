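#' Read a protein-level SILAC quantification table
#'
#' Reads one mass-spectrometry run's protein-level light/heavy (L/H)
#' quantification as exported downstream of the search engine: one row per
#' protein with its L/H intensity ratio and the number of quantified
#' peptide-ratio events (L/H count). Proteins with an L/H count of zero or a
#' missing ratio carry no usable quantification and are dropped on read;
#' only proteins with L/H count >= 1 enter the analysis.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param receptor Name of the nuclear transport receptor added to the
#'   reaction (e.g. `"Trn-1"`), or `NA` for a receptor-free control.
#' @param condition `"ntr"` for a +NTR run, `"ctl"` for its control.
#' @param replicate Replicate index (1-3).
#' @param col_names Named character vector mapping the canonical column roles
#'   `accession`, `lh_ratio` and `lh_count` to the header names used in the
#'   file. Search-engine exports vary; remap here rather than editing files.
#'
#' @return A tibble with columns `receptor`, `condition`, `replicate`,
#'   `accession`, `lh_ratio`, `lh_count` — one row per retained protein.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("accession\tlh_ratio\tlh_count",
#'              "P1\t1.2\t2", "P2\t0.8\t1", "P3\t2.0\t0"), tf)
#' read_quant_table(tf, receptor = "Trn-1", condition = "ntr", replicate = 1)
read_quant_table <- function(path, receptor = NA_character_,
                             condition = c("ntr", "ctl"), replicate,
                             col_names = c(accession = "accession",
                                           lh_ratio = "lh_ratio",
                                           lh_count = "lh_count")) {
  condition <- match.arg(condition)
  if (condition == "ntr" && (is.na(receptor) || !nzchar(receptor))) {
    stop_silactp("a +NTR run requires a non-empty `receptor` name",
                 "silactp_usage_error")
  }
  stopifnot(length(replicate) == 1L, replicate >= 1)
  raw <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         progress = FALSE)
  needed <- col_names[c("accession", "lh_ratio", "lh_count")]
  missing_cols <- setdiff(unname(needed), names(raw))
  if (length(missing_cols) > 0) {
    stop_silactp(
      paste0("quantification table ", path, " lacks column(s): ",
             paste(missing_cols, collapse = ", ")),
      "silactp_format_error")
  }
  tbl <- tibble(
    accession = as.character(raw[[needed[["accession"]]]]),
    lh_ratio  = as.numeric(raw[[needed[["lh_ratio"]]]]),
    lh_count  = as.integer(raw[[needed[["lh_count"]]]])
  )
  tbl <- dplyr::filter(tbl, !is.na(.data$lh_count), .data$lh_count >= 1L,
                       !is.na(.data$lh_ratio))
  dup <- tbl$accession[duplicated(tbl$accession)]
  if (length(dup) > 0) {
    stop_silactp(paste0("duplicate accession(s) in ", path, ": ",
                        paste(unique(dup), collapse = ", ")),
                 "silactp_data_error")
  }
  if (any(tbl$lh_ratio <= 0 | !is.finite(tbl$lh_ratio))) {
    bad <- tbl$accession[tbl$lh_ratio <= 0 | !is.finite(tbl$lh_ratio)]
    stop_silactp(paste0("non-positive or non-finite L/H ratio for: ",
                        paste(bad, collapse = ", ")),
                 "silactp_data_error")
  }
  tibble(receptor = receptor, condition = condition,
         replicate = as.integer(replicate)) %>%
    dplyr::cross_join(tbl)
}

#' Read reported-cargo and subcellular-localization annotation
#'
#' The evaluation module needs two annotation inputs: previously reported
#' cargoes per receptor (the positive examples) and a
#' subcellular-localization class per protein (to build the non-nuclear
#' negative universe). Proteins absent from the localization table, or with
#' unrecognized class strings, are treated as `undetermined`.
#'
#' @param reported_path TSV with columns `receptor`, `accession`.
#' @param localization_path TSV with columns `accession`, `class`, where
#'   class is one of `nuclear`, `non_nuclear`, `undetermined`.
#' @return A list of class `silac_annotations` with elements `reported`
#'   (tibble: receptor, accession) and `localization` (tibble: accession,
#'   class).
#' @export
read_annotations <- function(reported_path, localization_path) {
  rep_tbl <- readr::read_tsv(reported_path, show_col_types = FALSE,
                             comment = "#", progress = FALSE)
  loc_tbl <- readr::read_tsv(localization_path, show_col_types = FALSE,
                             comment = "#", progress = FALSE)
  for (col in c("receptor", "accession")) {
    if (!col %in% names(rep_tbl)) {
      stop_silactp(paste0("reported-cargo table lacks column ", col),
                   "silactp_format_error")
    }
  }
  for (col in c("accession", "class")) {
    if (!col %in% names(loc_tbl)) {
      stop_silactp(paste0("localization table lacks column ", col),
                   "silactp_format_error")
    }
  }
  loc <- tibble(
    accession = as.character(loc_tbl$accession),
    class = ifelse(loc_tbl$class %in% c("nuclear", "non_nuclear"),
                   as.character(loc_tbl$class), "undetermined")
  ) %>% distinct(.data$accession, .keep_all = TRUE)
  ann <- list(
    reported = distinct(tibble(receptor = as.character(rep_tbl$receptor),
                               accession = as.character(rep_tbl$accession))),
    localization = loc
  )
  class(ann) <- "silac_annotations"
  ann
}

#' Look up localization classes, defaulting to undetermined
#' @param annotations A `silac_annotations` list.
#' @param accessions Character vector of protein accessions.
#' @return Character vector of classes, same length as `accessions`.
#' @export
localization_class <- function(annotations, accessions) {
  idx <- match(accessions, annotations$localization$accession)
  cls <- annotations$localization$class[idx]
  cls[is.na(cls)] <- "undetermined"
  cls
}

#' Read protein sequences from FASTA
#'
#' Accessions are taken from the first whitespace-delimited token of each
#' header; for the UniProt `sp|ACC|NAME` dialect the middle field is used.
#' Sequences are upper-cased and trailing `*` terminators stripped.
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  seqs <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop_silactp(
      paste0("malformed FASTA ", path, ": ", conditionMessage(e)),
      "silactp_format_error")
  )
  acc <- vapply(strsplit(names(seqs), "[ \t]"), function(x) x[[1]], "",
                USE.NAMES = FALSE)
  sp <- grepl("^(sp|tr)\\|", acc)
  acc[sp] <- vapply(strsplit(acc[sp], "|", fixed = TRUE),
                    function(x) x[[2]], "")
  if (anyDuplicated(acc)) {
    stop_silactp(paste0("duplicate accession(s) in FASTA: ",
                        paste(unique(acc[duplicated(acc)]), collapse = ", ")),
                 "silactp_format_error")
  }
  out <- toupper(sub("\\*+$", "", as.character(seqs)))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYXUBZ]", out)
  if (any(bad)) {
    stop_silactp(paste0("invalid amino-acid letters in: ",
                        paste(acc[bad], collapse = ", ")),
                 "silactp_data_error")
  }
  setNames(out, acc)
}

# Shared TSV writer: a "#" comment line documents the column order, then a
# regular header so the files re-read with standard TSV tools.
write_silac_tsv <- function(tbl, path, what) {
  is_p <- grepl("(^|_)(p|fisher_p)$|p_value", names(tbl))
  out <- tbl
  for (j in which(is_p)) out[[j]] <- sprintf("%.6e", out[[j]])
  header <- paste0("# silactp ", what, "; columns: ",
                   paste(names(tbl), collapse = ", "))
  body <- readr::format_tsv(out)
  ok <- tryCatch({
    writeLines(c(header, sub("\n$", "", body)), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_silactp(paste0("cannot write ", path), "silactp_io_error")
  invisible(path)
}

#' Write / read a ranking table
#'
#' Tab-separated, one row per protein in rank order, with a leading `#`
#' comment line documenting the column order. `read_ranking()` restores the
#' tibble so that `read_ranking(write_ranking(x, p))` reproduces `x`.
#'
#' @param ranking A ranking tibble from [rank_proteins()].
#' @param path Output path.
#' @return `path`, invisibly (`write_ranking`); the ranking tibble
#'   (`read_ranking`).
#' @export
write_ranking <- function(ranking, path) {
  write_silac_tsv(ranking, path, "ranking")
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if ("rank" %in% names(tbl)) tbl$rank <- as.integer(tbl$rank)
  if ("n_values" %in% names(tbl)) tbl$n_values <- as.integer(tbl$n_values)
  if ("accession" %in% names(tbl)) tbl$accession <- as.character(tbl$accession)
  as_tibble(tbl)
}

#' Write an evaluation sweep table
#'
#' One row per percentile cutoff; p-values are serialized in scientific
#' notation with six significant digits.
#'
#' @param points An evaluation tibble from [evaluate_cutoffs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(points, path) {
  write_silac_tsv(points, path, "evaluation sweep")
}
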