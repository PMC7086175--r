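# Tabular readers/writers. Dialect: tab-separated, UTF-8, header row
# required, "#" comment lines ignored.

read_orgflux_tsv <- function(file, required, col_types = NULL) {
  df <- readr::read_tsv(file, comment = "#", col_types = col_types,
                        progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("missing required column(s) in ", file, ": ",
                 paste(missing, collapse = ", ")))
  }
  df
}

#' Read a subcellular localization table
#'
#' Reads the per-gene compartment assignments produced by an external
#' predictor (TargetP/PredAlgo-style output reshaped to TSV). Required
#' columns: `gene_id`, `compartment`; optional logical `dual_peroxisomal`.
#' Compartment strings must be one of [COMPARTMENTS].
#'
#' @param file Path to a TSV file.
#' @return A tibble with columns `gene_id`, `compartment`, `dual_peroxisomal`.
#' @export
read_localization_table <- function(file) {
  df <- read_orgflux_tsv(file, c("gene_id", "compartment"),
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0L) {
    warn(paste0("localization table ", file, " is empty"))
    return(tibble::tibble(gene_id = character(), compartment = character(),
                          dual_peroxisomal = logical()))
  }
  bad <- setdiff(unique(df$compartment), COMPARTMENTS)
  if (length(bad)) {
    abort(paste0("unknown compartment value(s): ", paste(bad, collapse = ", "),
                 "; allowed values are: ", paste(COMPARTMENTS, collapse = ", ")))
  }
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) {
    abort(paste0("duplicate gene_id in localization table: ",
                 paste(head(dup, 5L), collapse = ", ")))
  }
  dual <- if ("dual_peroxisomal" %in% names(df)) {
    toupper(df$dual_peroxisomal) %in% c("TRUE", "T", "1", "YES")
  } else {
    rep(FALSE, nrow(df))
  }
  tibble::tibble(gene_id = df$gene_id, compartment = df$compartment,
                 dual_peroxisomal = dual)
}

#' Read a gene-to-species map
#'
#' @param file TSV with columns `gene_id`, `species_id`.
#' @return A tibble.
#' @export
read_gene_species_map <- function(file) {
  df <- read_orgflux_tsv(file, c("gene_id", "species_id"),
                         col_types = readr::cols(.default = readr::col_character()))
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) {
    abort(paste0("duplicate gene_id in gene-species map: ",
                 paste(head(dup, 5L), collapse = ", ")))
  }
  tibble::as_tibble(df[c("gene_id", "species_id")])
}

#' Read a functional-annotation table
#'
#' @param file TSV with columns `gene_id`, `term`.
#' @return A tibble with one row per (gene, term) pair.
#' @export
read_terms_table <- function(file) {
  df <- read_orgflux_tsv(file, c("gene_id", "term"),
                         col_types = readr::cols(.default = readr::col_character()))
  dplyr::distinct(tibble::as_tibble(df[c("gene_id", "term")]))
}

#' Read protein sequences from a FASTA file
#'
#' @param file Path to an (uncompressed) amino-acid FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(file) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required to read FASTA files")
  }
  x <- Biostrings::readAAStringSet(file)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(sequences, file) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required to write FASTA files")
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), file)
  invisible(file)
}

#' Binary targeting states for one organelle
#'
#' Converts localization calls into the 0/1 trait analysed per organelle:
#' a gene is in state 1 when its compartment equals `organelle`, and
#' dual-peroxisomal genes count as present both for the peroxisome trait and
#' for their external compartment trait. Genes listed in `genes` but absent
#' from `calls` are treated as compartment "none" with a warning.
#'
#' @param calls Tibble as returned by [read_localization_table()].
#' @param organelle One of [ORGANELLES].
#' @param genes Optional character vector of gene ids that must be covered.
#' @return Named integer vector of 0/1 states.
#' @export
trait_states <- function(calls, organelle, genes = NULL) {
  organelle <- match.arg(organelle, ORGANELLES)
  if (!is.null(genes)) {
    missing <- setdiff(genes, calls$gene_id)
    if (length(missing)) {
      warn(paste0(length(missing), " gene(s) missing from localization calls; ",
                  "treated as compartment \"none\" (e.g. ",
                  paste(head(missing, 3L), collapse = ", "), ")"))
      calls <- dplyr::bind_rows(calls, tibble::tibble(
        gene_id = missing, compartment = "none", dual_peroxisomal = FALSE))
    }
    calls <- calls[calls$gene_id %in% genes, , drop = FALSE]
  }
  state <- as.integer(calls$compartment == organelle |
                        (organelle == "peroxisome" & calls$dual_peroxisomal))
  setNames(state, calls$gene_id)
}
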