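# Rule-based peroxisomal targeting-signal (PTS) classification.
#
# PTS1: one of nine accepted C-terminal tripeptides.
# PTS2: the nonapeptide R[LI]X5HL in the N-terminal region (residues 1-30).

#' The nine accepted PTS1 C-terminal tripeptides
#' @format Character vector of length 9.
#' @export
PTS1_TRIPEPTIDES <- c("SRL", "SRM", "SRI", "ARL", "ARM", "PRL", "SKL", "SKM", "AKL")

# One-letter amino-acid alphabet accepted on input (incl. ambiguity codes).
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYXBZJUO", "")[[1]]

# Uppercase, strip terminal whitespace and trailing stop symbols, validate.
clean_aa <- function(sequence) {
  s <- toupper(trimws(sequence))
  s <- sub("\\*+$", "", s)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), AA_ALPHABET)
  if (length(bad)) {
    abort(paste0("non-amino-acid character(s) in sequence: ",
                 paste(bad, collapse = ", ")))
  }
  s
}

#' Classify a protein sequence for a PTS1 signal
#'
#' A sequence carries a PTS1 when its final three residues equal one of the
#' nine accepted tripeptides ([PTS1_TRIPEPTIDES]). Matching is
#' case-insensitive; a trailing "*" stop symbol is stripped first. Ambiguity
#' codes (e.g. "X") never satisfy a motif position that requires a specific
#' residue.
#'
#' @param sequence One-letter amino-acid string.
#' @return A list with `pts1` (logical) and `motif` (the matched tripeptide,
#'   or `NA`).
#' @examples
#' classify_pts1("MAVQTPSKL")$pts1
#' @export
classify_pts1 <- function(sequence) {
  s <- clean_aa(sequence)
  if (nchar(s) < 3L) {
    inform("sequence shorter than 3 residues; PTS1 set to FALSE")
    return(list(pts1 = FALSE, motif = NA_character_))
  }
  tail3 <- substr(s, nchar(s) - 2L, nchar(s))
  hit <- tail3 %in% PTS1_TRIPEPTIDES
  list(pts1 = hit, motif = if (hit) tail3 else NA_character_)
}

#' Classify a protein sequence for a PTS2 signal
#'
#' A sequence carries a PTS2 when it contains the nonapeptide motif
#' R-\[LI\]-X5-H-L within the N-terminal region (residues 1-30). With
#' `anchor = "whole"` (default) the entire 9-mer must lie inside the window
#' (start position at most `window - 8`); with `anchor = "start"` only the
#' start position must fall inside the window. The leftmost qualifying match
#' is reported. "X" satisfies only the five wildcard positions.
#'
#' @param sequence One-letter amino-acid string.
#' @param window Last residue of the N-terminal region (default 30).
#' @param anchor `"whole"` (9-mer wholly within the window) or `"start"`
#'   (match may extend past it).
#' @return A list with `pts2` (logical) and `start` (1-based start of the
#'   motif, or `NA`).
#' @examples
#' classify_pts2("MARLQQQQQHLKED")$start  # 3
#' @export
classify_pts2 <- function(sequence, window = 30, anchor = c("whole", "start")) {
  anchor <- match.arg(anchor)
  s <- clean_aa(sequence)
  if (nchar(s) < 9L) return(list(pts2 = FALSE, start = NA_integer_))
  # restrict the subject so any regexpr match automatically obeys the window
  subject <- if (anchor == "whole") substr(s, 1L, window) else substr(s, 1L, window + 8L)
  m <- regexpr("R[LI].{5}HL", subject, perl = TRUE)
  start <- as.integer(m)
  ok <- start > 0L && (anchor == "whole" || start <= window)
  list(pts2 = ok, start = if (ok) start else NA_integer_)
}

#' Scan a set of protein sequences for PTS1/PTS2 signals
#'
#' Vectorised front end to [classify_pts1()] and [classify_pts2()].
#'
#' @param sequences Named character vector of amino-acid sequences (names are
#'   gene ids), e.g. from [read_fasta()].
#' @param window,anchor Passed to [classify_pts2()].
#' @return A tibble with columns `gene_id`, `pts1`, `pts2`, `motif`, `start`.
#' @export
scan_pts <- function(sequences, window = 30, anchor = c("whole", "start")) {
  anchor <- match.arg(anchor)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    abort("`sequences` must be a named character vector")
  }
  r1 <- lapply(sequences, classify_pts1)
  r2 <- lapply(sequences, classify_pts2, window = window, anchor = anchor)
  tibble::tibble(
    gene_id = names(sequences),
    pts1 = unname(vapply(r1, `[[`, logical(1), "pts1")),
    pts2 = unname(vapply(r2, `[[`, logical(1), "pts2")),
    motif = unname(vapply(r1, `[[`, character(1), "motif")),
    start = unname(vapply(r2, `[[`, integer(1), "start"))
  )
}

#' Merge external localization predictions with PTS scan results
#'
#' Applies the dual-localization rule: a protein with a PTS and a positive
#' external organellar prediction (chloroplast, mitochondrion or secretory)
#' keeps its external compartment and is flagged dual-peroxisomal; a protein
#' with a PTS and no external prediction is assigned to the peroxisome; a
#' protein without a PTS keeps its external call unchanged. The operation is
#' idempotent.
#'
#' @param calls Tibble of localization calls (`gene_id`, `compartment`,
#'   `dual_peroxisomal`), e.g. from [read_localization_table()].
#' @param pts Tibble from [scan_pts()].
#' @return A tibble with the same columns as `calls`.
#' @export
merge_localization <- function(calls, pts) {
  stopifnot(all(c("gene_id", "compartment") %in% names(calls)),
            all(c("gene_id", "pts1", "pts2") %in% names(pts)))
  if (!"dual_peroxisomal" %in% names(calls)) calls$dual_peroxisomal <- FALSE
  out <- dplyr::left_join(
    tibble::as_tibble(calls),
    dplyr::transmute(pts, gene_id = .data$gene_id,
                     has_pts = .data$pts1 | .data$pts2),
    by = "gene_id"
  )
  out$has_pts[is.na(out$has_pts)] <- FALSE
  ext_org <- out$compartment %in% c("chloroplast", "mitochondrion", "secretory")
  out$dual_peroxisomal <- out$dual_peroxisomal | (out$has_pts & ext_org)
  out$compartment[out$has_pts & out$compartment == "none"] <- "peroxisome"
  dplyr::select(out, -"has_pts")
}
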