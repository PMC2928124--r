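#' Read an annotated single-pass protein set
#'
#' Reads protein sequences from a FASTA file and per-protein annotations from
#' a tab-separated table with columns
#' `id  topology  organelle  tmd_start  tmd_end  species` (header required,
#' `species` optional). `tmd_start`/`tmd_end` give the guide TMD interval,
#' 1-based inclusive on the N-to-C sequence. Records failing validation
#' (sequence containing nonstandard letters B/Z/X/U/O/J, guide interval out
#' of bounds or shorter than 10 residues, unknown topology) are rejected:
#' either dropped with a warning naming each id, or raised as errors.
#' FASTA records not referenced by the annotation table are ignored with a
#' warning; annotation rows referencing ids absent from the FASTA are an
#' error naming the id.
#'
#' @param fasta_path Path to a FASTA file of amino-acid sequences.
#' @param annotation_path Path to the TSV annotation table.
#' @param on_invalid `"drop"` (default) to discard invalid records with a
#'   warning, `"error"` to stop at the first invalid record.
#' @return A tibble with one row per protein and columns `id`, `sequence`,
#'   `topology`, `organelle`, `tmd_start`, `tmd_end`, `species`. An empty
#'   annotation table yields a zero-row tibble.
#' @seealso [write_protein_set()], [sample_dataset()]
#' @export
read_protein_set <- function(fasta_path, annotation_path, on_invalid = c("drop", "error")) {
  on_invalid <- match.arg(on_invalid)
  seqs <- Biostrings::readAAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  annot <- readr::read_tsv(
    annotation_path,
    col_types = readr::cols(
      id = readr::col_character(),
      topology = readr::col_character(),
      organelle = readr::col_character(),
      tmd_start = readr::col_integer(),
      tmd_end = readr::col_integer(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  required <- c("id", "topology", "organelle", "tmd_start", "tmd_end")
  missing_cols <- setdiff(required, names(annot))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"species" %in% names(annot)) {
    annot$species <- NA_character_
  }
  if (nrow(annot) == 0) {
    unused <- names(seqs)
    if (length(unused) > 0) {
      warn(sprintf("%d FASTA record(s) not referenced by the annotation table; ignored",
                   length(unused)))
    }
    return(tibble(id = character(), sequence = character(),
                  topology = character(), organelle = character(),
                  tmd_start = integer(), tmd_end = integer(),
                  species = character()))
  }

  absent <- setdiff(annot$id, names(seqs))
  if (length(absent) > 0) {
    abort(paste0("annotation references id(s) absent from FASTA: ",
                 paste(absent, collapse = ", ")))
  }
  unused <- setdiff(names(seqs), annot$id)
  if (length(unused) > 0) {
    warn(sprintf("%d FASTA record(s) not referenced by the annotation table; ignored",
                 length(unused)))
  }

  proteins <- annot %>%
    select("id", "topology", "organelle", "tmd_start", "tmd_end", "species") %>%
    mutate(sequence = unname(as.character(seqs[.data$id])), .after = "id")
  validate_proteins(proteins, on_invalid = on_invalid)
}

#' Validate a protein tibble
#'
#' Checks the invariants every downstream operation relies on: standard
#' 20-letter sequences, topology in I/II/III, guide interval inside the
#' sequence and at least 10 residues long, unique ids.
#'
#' @param proteins Tibble with columns `id`, `sequence`, `topology`,
#'   `organelle`, `tmd_start`, `tmd_end` (and optionally `species`).
#' @param on_invalid `"drop"` or `"error"`.
#' @return The validated (possibly reduced) tibble.
#' @export
validate_proteins <- function(proteins, on_invalid = c("drop", "error")) {
  on_invalid <- match.arg(on_invalid)
  if (anyDuplicated(proteins$id)) {
    abort(paste0("duplicated protein id(s): ",
                 paste(unique(proteins$id[duplicated(proteins$id)]), collapse = ", ")))
  }
  reasons <- purrr::pmap_chr(proteins, function(id, sequence, topology,
                                                tmd_start, tmd_end, ...) {
    if (is.na(sequence)) return("missing sequence")
    chars <- unique(strsplit(sequence, "")[[1]])
    bad <- setdiff(chars, AA_ALPHABET)
    if (length(bad) > 0) {
      return(paste0("nonstandard residue(s): ", paste(bad, collapse = ", ")))
    }
    if (!topology %in% c("I", "II", "III")) {
      return(paste0("unknown topology '", topology, "'"))
    }
    if (is.na(tmd_start) || is.na(tmd_end)) return("malformed guide interval")
    if (tmd_start < 1 || tmd_end > nchar(sequence) || tmd_start > tmd_end) {
      return(sprintf("guide interval [%s,%s] out of bounds for length %d",
                     tmd_start, tmd_end, nchar(sequence)))
    }
    if (tmd_end - tmd_start + 1 < 10) return("guide interval shorter than 10 residues")
    NA_character_
  })
  bad <- !is.na(reasons)
  if (any(bad)) {
    msgs <- paste0(proteins$id[bad], ": ", reasons[bad])
    if (on_invalid == "error") {
      abort(paste0("invalid protein record(s):\n  ", paste(msgs, collapse = "\n  ")))
    }
    warn(paste0("dropped ", sum(bad), " invalid record(s):\n  ",
                paste(msgs, collapse = "\n  ")))
  }
  proteins[!bad, , drop = FALSE]
}

#' Write a protein set as FASTA plus annotation TSV
#'
#' Inverse of [read_protein_set()]; coordinates are written 1-based
#' inclusive.
#'
#' @param proteins Protein tibble.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, `proteins`.
#' @export
write_protein_set <- function(proteins, fasta_path, annotation_path) {
  seqs <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  out <- proteins %>% select("id", "topology", "organelle",
                             "tmd_start", "tmd_end", dplyr::any_of("species"))
  if (!"species" %in% names(out)) out$species <- NA_character_
  readr::write_tsv(out, annotation_path, progress = FALSE)
  invisible(proteins)
}

#' Split a protein tibble into per-organelle datasets
#'
#' @param proteins Protein tibble.
#' @return A named list of tibbles, one per distinct organelle label.
#' @export
split_by_organelle <- function(proteins) {
  if (nrow(proteins) == 0) return(list())
  split(proteins, proteins$organelle)
}
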