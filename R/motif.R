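#' Declarative sequence motif pattern
#'
#' Patterns are ordered lists of elements matched left to right against the
#' amino-acid sequence, with backtracking over variable-length gaps:
#'
#' * `el_set(residues, min = 1, max = min)` — a run of `min`..`max`
#'   residues drawn from the allowed set;
#' * `el_gap(min, max)` — `min`..`max` arbitrary residues (bounded gap;
#'   unbounded repeats are deliberately not supported);
#' * `el_window(residues, width, min_count)` — a fixed-width window
#'   containing at least `min_count` residues from the set (e.g. a
#'   basic-enriched stretch: >= 4 of K/R within 6 consecutive residues).
#'
#' Element lists serialize naturally to/from YAML ([read_patterns()],
#' [write_patterns()]).
#'
#' @param name Pattern name.
#' @param elements List of elements built with `el_set()`, `el_gap()`,
#'   `el_window()`.
#' @return A `motif_pattern` object.
#' @export
motif_pattern <- function(name, elements) {
  stopifnot(is.character(name), length(elements) >= 1)
  for (el in elements) {
    if (!is.list(el) || !el$type %in% c("set", "gap", "window")) {
      stop_silactp("elements must be built with el_set/el_gap/el_window",
                   "silactp_usage_error")
    }
    if (el$type != "window" && (el$min > el$max || el$max > 1000)) {
      stop_silactp("element repeats must be bounded with min <= max",
                   "silactp_usage_error")
    }
  }
  structure(list(name = name, elements = elements), class = "motif_pattern")
}

#' @rdname motif_pattern
#' @param residues String of allowed single-letter residues.
#' @param min,max Repeat bounds.
#' @export
el_set <- function(residues, min = 1L, max = min) {
  list(type = "set", residues = toupper(residues),
       min = as.integer(min), max = as.integer(max))
}

#' @rdname motif_pattern
#' @export
el_gap <- function(min, max) {
  list(type = "gap", min = as.integer(min), max = as.integer(max))
}

#' @rdname motif_pattern
#' @param width Window width in residues.
#' @param min_count Minimum number of allowed residues within the window.
#' @export
el_window <- function(residues, width, min_count) {
  stopifnot(min_count <= width)
  list(type = "window", residues = toupper(residues),
       width = as.integer(width), min_count = as.integer(min_count))
}

#' @rdname motif_pattern
#' @param literal A literal residue string, e.g. `"SRSRSR"`.
#' @export
literal_pattern <- function(name, literal) {
  motif_pattern(name, lapply(strsplit(toupper(literal), "")[[1]],
                             function(ch) el_set(ch)))
}

#' Default motif patterns: PY-NLS variants and the SR hexapeptide
#'
#' The PY-NLS recognized by transportin-1/2 consists of an N-terminal
#' element — either a hydrophobic block (phi-G/A/S-phi-phi with phi one of
#' W/F/Y/L/I/V/M) or a basic-enriched stretch (at least 4 of K/R within 6
#' consecutive residues) — followed after a bounded linker by the
#' C-terminal R/K/H-X(2-5)-P-Y element. The serine/arginine hexapeptide
#' `SRSRSR` marks SR-rich splicing-factor domains. Every residue class and
#' gap bound is data, not code: edit the returned objects or supply a YAML
#' file to change them.
#'
#' @param linker_max Maximum residues between the N-terminal element and
#'   the C-terminal R/K/H (default 15).
#' @return Named list of `motif_pattern` objects: `py_nls_hydrophobic`,
#'   `py_nls_basic`, `sr_repeat`.
#' @export
default_patterns <- function(linker_max = 15L) {
  phi <- "WFYLIVM"
  cterm <- list(el_set("RKH"), el_gap(2L, 5L), el_set("P"), el_set("Y"))
  list(
    py_nls_hydrophobic = motif_pattern(
      "py_nls_hydrophobic",
      c(list(el_set(phi), el_set("GAS"), el_set(phi), el_set(phi),
             el_gap(0L, linker_max)), cterm)),
    py_nls_basic = motif_pattern(
      "py_nls_basic",
      c(list(el_window("KR", 6L, 4L), el_gap(0L, linker_max)), cterm)),
    sr_repeat = literal_pattern("sr_repeat", "SRSRSR")
  )
}

# Recursive matcher: try to match elements[i..] starting at pos (1-based)
# in the residue vector; returns the smallest end position of a complete
# match or NA. Backtracks over gap/repeat lengths shortest-first, so the
# reported hit at a start is the leftmost-ending one.
match_from <- function(res, pos, elements, i) {
  if (i > length(elements)) return(pos - 1L)
  el <- elements[[i]]
  n <- length(res)
  if (el$type == "window") {
    end <- pos + el$width - 1L
    if (end > n) return(NA_integer_)
    hits <- sum(res[pos:end] %in% strsplit(el$residues, "")[[1]])
    if (hits < el$min_count) return(NA_integer_)
    return(match_from(res, end + 1L, elements, i + 1L))
  }
  allowed <- if (el$type == "set") strsplit(el$residues, "")[[1]] else NULL
  for (len in el$min:el$max) {
    end <- pos + len - 1L
    if (end > n) break
    if (!is.null(allowed) && len > 0 &&
        !all(res[pos:end] %in% allowed)) break
    found <- match_from(res, end + 1L, elements, i + 1L)
    if (!is.na(found)) return(found)
  }
  NA_integer_
}

#' Scan sequences for motif hits
#'
#' Reports one hit per matching start position (leftmost-ending match at
#' each start), left to right. Coordinates are 1-based inclusive residue
#' positions. Scanning each sequence is independent of input order.
#'
#' @param sequences Named character vector of amino-acid sequences
#'   ([read_fasta()]).
#' @param patterns A `motif_pattern`, or list of them
#'   ([default_patterns()]).
#' @return A tibble of hits: `accession`, `pattern`, `start`, `end`.
#' @export
#' @examples
#' scan_motifs(c(A1 = "AASRSRSRGG"), default_patterns()["sr_repeat"])
scan_motifs <- function(sequences, patterns) {
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  purrr::map_dfr(seq_along(sequences), function(si) {
    res <- strsplit(sequences[[si]], "")[[1]]
    acc <- names(sequences)[si] %||% as.character(si)
    purrr::map_dfr(patterns, function(pat) {
      if (length(res) == 0) {
        return(tibble(accession = character(), pattern = character(),
                      start = integer(), end = integer()))
      }
      starts <- integer()
      ends <- integer()
      for (pos in seq_along(res)) {
        e <- match_from(res, pos, pat$elements, 1L)
        if (!is.na(e) && e >= pos) {
          starts <- c(starts, pos)
          ends <- c(ends, e)
        }
      }
      tibble(accession = acc, pattern = pat$name, start = starts, end = ends)
    })
  })
}

#' Motif-positive accessions
#'
#' A protein is motif-positive when it has at least one hit for any of the
#' given patterns (by default, either PY-NLS variant).
#'
#' @param hits Hit tibble from [scan_motifs()].
#' @param patterns Character vector of pattern names to count (default:
#'   all in `hits`).
#' @return Character vector of accessions.
#' @export
motif_positive <- function(hits, patterns = NULL) {
  if (!is.null(patterns)) {
    hits <- dplyr::filter(hits, .data$pattern %in% patterns)
  }
  unique(hits$accession)
}

#' Sliding-window motif density along a ranking
#'
#' The percentage of motif-positive proteins among each run of `window`
#' consecutively ranked proteins, stride 1: the value at position 1 covers
#' ranks 1..window, so 19 positives in the top 50 gives 38% at position 1.
#'
#' @param ranking A `silac_ranking` tibble (or any tibble with `accession`
#'   in rank order).
#' @param positives Character vector of motif-positive accessions.
#' @param window Window width in ranks (default 50).
#' @return A `density_profile` tibble: `position` (first rank of the
#'   window, 1..N-window+1), `pct` in \[0, 100\].
#' @export
windowed_density <- function(ranking, positives, window = 50L) {
  acc <- ranking$accession
  n <- length(acc)
  if (window > n) {
    stop_silactp("window exceeds ranking size", "silactp_usage_error")
  }
  ind <- as.numeric(acc %in% positives)
  counts <- cumsum(ind)
  counts <- counts[window:n] - c(0, counts)[1:(n - window + 1L)]
  out <- tibble(position = seq_len(n - window + 1L),
                pct = 100 * counts / window)
  class(out) <- c("density_profile", class(out))
  attr(out, "window") <- as.integer(window)
  out
}

#' Read / write motif patterns as YAML
#'
#' @param path YAML file path.
#' @param patterns Named list of `motif_pattern` objects.
#' @return A named list of `motif_pattern`s (`read_patterns`); `path`
#'   invisibly (`write_patterns`).
#' @export
read_patterns <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    motif_pattern(nm, lapply(raw[[nm]], function(el) {
      el$min <- if (!is.null(el$min)) as.integer(el$min)
      el$max <- if (!is.null(el$max)) as.integer(el$max)
      el$width <- if (!is.null(el$width)) as.integer(el$width)
      el$min_count <- if (!is.null(el$min_count)) as.integer(el$min_count)
      el
    }))
  })
  setNames(out, names(raw))
}

#' @rdname read_patterns
#' @export
write_patterns <- function(patterns, path) {
  yaml::write_yaml(lapply(patterns, function(p) p$elements), path)
  invisible(path)
}
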