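#' Read coding sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) nucleotide FASTA file into a tibble.
#' Sequences are normalized: whitespace inside records is dropped, lowercase
#' is mapped to uppercase and RNA `U` is mapped to `T`. The record id is the
#' header token before the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`. Zero-record files give
#'   a zero-row tibble.
#' @seealso [qc_filter_cds()], [write_cds_fasta()]
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(!grepl("^[[:space:]]*$", lines))
  if (length(nonblank) == 0) {
    return(tibble::tibble(id = character(), sequence = character()))
  }
  if (!startsWith(lines[nonblank[1]], ">")) {
    stop("malformed FASTA: sequence data before first header at line ",
         nonblank[1], call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  id <- sub("\\s.*$", "", names(set))
  dup <- id[duplicated(id)]
  if (length(dup) > 0) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seq <- chartr("U", "T", toupper(gsub("[[:space:]]", "", as.character(set))))
  empty <- id[!nzchar(seq)]
  if (length(empty) > 0) {
    stop("empty sequence for id(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(id = id, sequence = unname(seq))
}

#' Write coding sequences to a FASTA file
#'
#' @param cds Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path, width = 70) {
  set <- Biostrings::DNAStringSet(stats::setNames(cds$sequence, cds$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Quality-filter coding sequences
#'
#' Applies the standard CDS sanity filter used before codon-usage analysis:
#' a sequence passes iff its length is a multiple of 3, it contains no
#' ambiguous base (anything outside A/C/G/T), it begins with the initiation
#' codon ATG, ends with a termination codon (TAA/TAG/TGA), contains no
#' internal termination codon, and encodes at least `min_aa` amino acids
#' (non-stop codons). Failing sequences are reported, not dropped silently:
#' each is assigned the first failing check in the order
#' `not_multiple_of_3`, `ambiguous_base`, `no_start`, `no_stop`,
#' `internal_stop`, `too_short`.
#'
#' @param seqs Tibble with columns `id`, `sequence` (e.g. from
#'   [read_cds_fasta()]).
#' @param min_aa Minimum number of non-stop codons (default 100).
#' @return An object of class `cds_qc`: a list with
#'   * `cds`: tibble of passing sequences (`id`, `sequence`, `length_aa`),
#'   * `report`: list with `n_input`, `n_passed` and a `rejections` tibble
#'     (`id`, `reason`).
#'   Use [tidy()][generics::tidy] for the rejections and
#'   [glance()][generics::glance] for the counts.
#' @examples
#' seqs <- tibble::tibble(
#'   id = c("ok", "bad"),
#'   sequence = c(paste0("ATG", strrep("AAA", 100), "TGA"), "ATGTAA")
#' )
#' qc <- qc_filter_cds(seqs, min_aa = 100)
#' glance(qc)
#' @export
qc_filter_cds <- function(seqs, min_aa = 100) {
  stopifnot(is.data.frame(seqs), all(c("id", "sequence") %in% names(seqs)),
            min_aa >= 1)
  reason <- vapply(seqs$sequence, qc_reason, character(1), min_aa = min_aa,
                   USE.NAMES = FALSE)
  pass <- is.na(reason)
  cds <- tibble::tibble(
    id = seqs$id[pass],
    sequence = seqs$sequence[pass],
    length_aa = nchar(seqs$sequence[pass]) %/% 3L - 1L
  )
  rejections <- tibble::tibble(id = seqs$id[!pass], reason = reason[!pass])
  structure(
    list(cds = cds,
         report = list(n_input = nrow(seqs), n_passed = nrow(cds),
                       rejections = rejections)),
    class = "cds_qc"
  )
}

# First failing QC check, NA if the sequence passes.
qc_reason <- function(sequence, min_aa) {
  n <- nchar(sequence)
  if (n %% 3L != 0L) return("not_multiple_of_3")
  if (grepl("[^ACGT]", sequence)) return("ambiguous_base")
  codons <- codon_split(sequence)
  if (codons[1] != "ATG") return("no_start")
  if (!codons[length(codons)] %in% STOP_CODONS) return("no_stop")
  body <- codons[-length(codons)]
  if (any(body %in% STOP_CODONS)) return("internal_stop")
  if (length(body) < min_aa) return("too_short")
  NA_character_
}

# Split an in-frame sequence into its codons.
codon_split <- function(sequence) {
  substring(sequence, seq(1, nchar(sequence) - 2, by = 3),
            seq(3, nchar(sequence), by = 3))
}

#' @export
print.cds_qc <- function(x, ...) {
  cat("CDS quality filter: ", x$report$n_passed, " of ", x$report$n_input,
      " sequences passed\n", sep = "")
  if (nrow(x$report$rejections) > 0) {
    tab <- table(x$report$rejections$reason)
    for (r in names(tab)) cat("  ", r, ": ", tab[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' @rdname qc_filter_cds
#' @param x A `cds_qc` object.
#' @param ... Unused.
#' @method tidy cds_qc
#' @export
tidy.cds_qc <- function(x, ...) x$report$rejections

#' @rdname qc_filter_cds
#' @method glance cds_qc
#' @export
glance.cds_qc <- function(x, ...) {
  tibble::tibble(
    n_input = x$report$n_input,
    n_passed = x$report$n_passed,
    n_rejected = nrow(x$report$rejections)
  )
}

#' Write a QC rejection report as TSV
#'
#' @param qc A `cds_qc` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  utils::write.table(tidy(qc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Count codons per gene
#'
#' Tallies in-frame codon usage for each coding sequence. The terminal stop
#' codon is excluded unless `include_stop = TRUE`; post-QC sequences contain
#' no internal stops, so with the default all stop-codon columns are zero.
#'
#' @param cds Tibble with columns `id`, `sequence` (QC-passed CDS).
#' @param include_stop Count the terminal stop codon too?
#' @return A wide tibble: `id` plus one integer column per codon (all 64,
#'   alphabetical).
#' @examples
#' cds <- tibble::tibble(id = "g1", sequence = "ATGAAAAAATGA")
#' counts <- count_codons(cds)
#' counts$AAA
#' @export
count_codons <- function(cds, include_stop = FALSE) {
  stopifnot(is.data.frame(cds), all(c("id", "sequence") %in% names(cds)))
  if (nrow(cds) == 0) {
    m <- matrix(integer(), 0, 64, dimnames = list(NULL, all_codons()))
  } else {
    set <- Biostrings::DNAStringSet(cds$sequence)
    m <- Biostrings::oligonucleotideFrequency(set, width = 3, step = 3)
    if (!include_stop) {
      last <- substring(cds$sequence, nchar(cds$sequence) - 2)
      hit <- which(last %in% STOP_CODONS)
      idx <- match(last[hit], colnames(m))
      m[cbind(hit, idx)] <- m[cbind(hit, idx)] - 1L
    }
  }
  dplyr::bind_cols(tibble::tibble(id = cds$id), tibble::as_tibble(m))
}
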