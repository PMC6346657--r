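## LabeledAlignment: haploid sequences plus a sample -> deme assignment.
## Sequences are stored as an integer matrix (samples x sites) coding
## A=1, C=2, G=3, T=4; NA marks missing/ambiguous sites.

#' Construct a labeled alignment
#'
#' @param seq integer matrix (samples x sites, codes 1..4 for A,C,G,T) or
#'   character matrix of bases
#' @param deme integer vector assigning each sample to a deme in
#'   `1..n_demes`
#' @param ids sample identifiers (default `deme{D}_ind{I}` style names)
#' @param lattice numeric lattice coordinate per deme (defaults to
#'   `1..n_demes`)
#' @param deme_names optional deme labels
#' @return an object of class `labeled_alignment`
#' @export
labeled_alignment <- function(seq, deme, ids = NULL, lattice = NULL,
                              deme_names = NULL) {
  if (is.character(seq)) {
    seq <- matrix(match(toupper(seq), DNA_BASES), nrow(seq), ncol(seq))
  }
  deme <- as.integer(deme)
  stopifnot(is.matrix(seq), nrow(seq) == length(deme), all(deme >= 1L))
  n_demes <- max(deme)
  if (!all(tabulate(deme, n_demes) >= 1L))
    stop("every deme must have at least one sample")
  ids <- ids %||% sprintf("deme%d_ind%d", deme,
                          stats::ave(deme, deme, FUN = seq_along))
  lattice <- lattice %||% seq_len(n_demes)
  deme_names <- deme_names %||% sprintf("deme%d", seq_len(n_demes))
  stopifnot(length(lattice) == n_demes, length(ids) == nrow(seq))
  rownames(seq) <- ids
  structure(list(seq = seq, deme = deme, ids = ids, lattice = lattice,
                 deme_names = deme_names, n_demes = n_demes),
            class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat(sprintf("labeled_alignment: %d sequences x %d bp, %d demes\n",
              nrow(x$seq), ncol(x$seq), x$n_demes))
  cat(sprintf("  variable sites: %d (%.1f%%)\n",
              round(prop_variable_sites(x) * ncol(x$seq)),
              100 * prop_variable_sites(x)))
  invisible(x)
}

#' Proportion of variable (segregating) sites
#'
#' @param aln a `labeled_alignment`
#' @return fraction of columns with more than one observed base
#' @export
prop_variable_sites <- function(aln) {
  v <- apply(aln$seq, 2, function(col) {
    u <- unique(col[!is.na(col)])
    length(u) > 1L
  })
  mean(v)
}

seq_as_char <- function(seq) {
  ch <- matrix(DNA_BASES[seq], nrow(seq), ncol(seq))
  ch[is.na(ch)] <- "N"
  apply(ch, 1, paste0, collapse = "")
}

#' Write an alignment as FASTA plus a deme-map TSV
#'
#' The TSV has columns `sample_id`, `deme`, `lattice_position`.
#'
#' @param aln a `labeled_alignment`
#' @param fasta,tsv output paths
#' @return invisibly, the FASTA path
#' @export
write_alignment <- function(aln, fasta, tsv = NULL) {
  lines <- rbind(paste0(">", aln$ids), seq_as_char(aln$seq))
  writeLines(as.vector(lines), fasta)
  if (!is.null(tsv)) {
    df <- data.frame(sample_id = aln$ids,
                     deme = aln$deme_names[aln$deme],
                     lattice_position = aln$lattice[aln$deme])
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}

#' Read a FASTA alignment plus a deme-map TSV
#'
#' Case is collapsed; characters outside ACGT are rejected unless
#' `map_ambiguous = TRUE`, in which case they become missing (NA).
#'
#' @param fasta path to an aligned FASTA file
#' @param tsv path to a TSV with columns `sample_id`, `deme` and optionally
#'   `lattice_position`
#' @param map_ambiguous treat non-ACGT characters as missing instead of
#'   erroring
#' @return a `labeled_alignment`
#' @export
read_alignment <- function(fasta, tsv, map_ambiguous = FALSE) {
  lines <- readLines(fasta)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", fasta)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste0(lines[(hdr[i] + 1L):ends[i]], collapse = ""), "")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences are not aligned (unequal lengths)")
  chars <- matrix(toupper(unlist(strsplit(seqs, ""))), length(seqs), L,
                  byrow = TRUE)
  codes <- matrix(match(chars, DNA_BASES), length(seqs), L)
  if (anyNA(codes) && !map_ambiguous)
    stop("non-ACGT characters present; set map_ambiguous = TRUE to treat ",
         "them as missing")

  map <- utils::read.table(tsv, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "deme") %in% names(map)))
    stop("deme map must have columns sample_id and deme")
  missing_ids <- setdiff(ids, map$sample_id)
  if (length(missing_ids))
    stop("samples absent from deme map: ", paste(missing_ids, collapse = ", "))
  map <- map[match(ids, map$sample_id), ]
  deme_names <- unique(map$deme)
  deme <- match(map$deme, deme_names)
  lattice <- if ("lattice_position" %in% names(map)) {
    vapply(deme_names, function(d)
      map$lattice_position[match(d, map$deme)], 0)
  } else seq_along(deme_names)
  labeled_alignment(codes, deme, ids = ids, lattice = lattice,
                    deme_names = deme_names)
}

#' Write a migrate-n classic infile
#'
#' Plain-text exchange format for cross-checking against migrate-n itself:
#' a header line `<n_demes> <n_loci>`, a line with the locus length, then
#' per-deme blocks headed by `<n_samples> <deme_name>`.
#'
#' @param aln a `labeled_alignment`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_migrate_infile <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d 1 Stepping-stone export", aln$n_demes), con)
  writeLines(sprintf("%d", ncol(aln$seq)), con)
  chars <- seq_as_char(aln$seq)
  for (d in seq_len(aln$n_demes)) {
    idx <- which(aln$deme == d)
    writeLines(sprintf("%d %s", length(idx), aln$deme_names[d]), con)
    writeLines(sprintf("%-10s%s", substr(aln$ids[idx], 1, 10), chars[idx]),
               con)
  }
  invisible(path)
}
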