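#' Describe the position of the spacer within a read
#'
#' A read layout places the 20-nt spacer either at a fixed 0-based offset
#' from the start of the read, or immediately after the first occurrence of
#' a constant anchor sequence (e.g. the 3' end of the U6 scaffold priming
#' site). Used both to generate synthetic reads ([simulate_fastq()]) and to
#' extract spacers when counting ([count_spacers()]).
#'
#' @param offset 0-based offset of the spacer (offset mode), or of the
#'   anchor when `anchor` is given.
#' @param anchor Optional constant ACGT sequence directly preceding the
#'   spacer.
#' @param read_length Total read length for generated reads; defaults to
#'   the minimum needed to hold prefix, anchor and spacer.
#' @param spacer_length Spacer length in nucleotides.
#' @return An object of class `fastq_layout`.
#' @examples
#' fastq_layout()                      # spacer at the very start of the read
#' fastq_layout(anchor = "ACCG")       # spacer right after the ACCG anchor
#' @export
fastq_layout <- function(offset = 0L, anchor = NULL, read_length = NULL,
                         spacer_length = 20L) {
  stopifnot(offset >= 0, spacer_length >= 1)
  if (!is.null(anchor)) {
    anchor <- toupper(anchor)
    if (!nzchar(anchor) || grepl("[^ACGT]", anchor))
      stop("anchor must be a non-empty ACGT sequence")
  }
  needed <- offset + sum(nchar(anchor)) + spacer_length
  if (is.null(read_length)) read_length <- needed
  if (read_length < needed)
    stop("read_length (", read_length, ") too short for the layout: ",
         "offset + anchor + spacer needs ", needed, " nt")
  structure(list(offset = as.integer(offset), anchor = anchor,
                 read_length = as.integer(read_length),
                 spacer_length = as.integer(spacer_length)),
            class = "fastq_layout")
}

#' Simulate FASTQ reads from a count table
#'
#' Writes exactly `count` reads carrying each guide's spacer, arranged
#' according to `layout`, with constant Phred+33 qualities. Context bases
#' (before/after the spacer) are random; in anchor mode they are re-drawn
#' if they would create a spurious earlier anchor occurrence, so
#' [count_spacers()] on the output reproduces the input table exactly.
#'
#' @param counts Named integer vector of reads per guide, or a data frame
#'   with columns `guide_id` and `count`.
#' @param library The `sgrna_library` providing spacer sequences.
#' @param path Output FASTQ path (gzip-compressed if it ends in `.gz`).
#' @param layout A [fastq_layout()].
#' @param seed Seed for the random context bases.
#' @return `path`, invisibly.
#' @export
simulate_fastq <- function(counts, library, path, layout = fastq_layout(),
                           seed = 1L) {
  stopifnot(inherits(library, "sgrna_library"),
            inherits(layout, "fastq_layout"))
  if (is.data.frame(counts)) {
    stopifnot(all(c("guide_id", "count") %in% names(counts)))
    counts <- setNames(counts$count, counts$guide_id)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  unknown <- setdiff(names(counts), library$guide_id)
  if (length(unknown))
    stop("counts reference guides absent from library: ",
         paste(unknown, collapse = ", "))
  if (layout$spacer_length != nchar(library$spacer[1L]))
    stop("layout spacer_length does not match the library's spacers")
  counts <- counts[counts > 0]
  guide <- rep(names(counts), counts)
  spacer <- library$spacer[match(guide, library$guide_id)]
  n <- length(spacer)
  reads <- with_rng_state(rng_stream_state(seed, 1L),
                          assemble_reads(spacer, layout))
  seqs <- Biostrings::DNAStringSet(reads)
  names(seqs) <- if (n > 0) paste0("read", seq_len(n), ":", guide)
                 else character(0)
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
  Biostrings::writeXStringSet(seqs, filepath = path, format = "fastq",
                              qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# Random context of given width for each of n reads.
random_context <- function(n, width) {
  if (n == 0L) return(character(0))
  if (width == 0L) return(rep("", n))
  paste_rows(matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
                    nrow = n))
}

paste_rows <- function(m) apply(m, 1L, paste, collapse = "")

assemble_reads <- function(spacer, layout) {
  n <- length(spacer)
  if (n == 0L) return(character(0))
  anchor <- layout$anchor
  prefix <- random_context(n, layout$offset)
  core_len <- layout$offset + sum(nchar(anchor)) + layout$spacer_length
  suffix <- random_context(n, layout$read_length - core_len)
  reads <- paste0(prefix, anchor, spacer, suffix)
  if (!is.null(anchor)) {
    # the anchor must first occur exactly where intended
    for (iter in 1:100) {
      pos <- regexpr(anchor, reads, fixed = TRUE)
      bad <- pos != layout$offset + 1L
      if (!any(bad)) break
      prefix[bad] <- random_context(sum(bad), layout$offset)
      reads[bad] <- paste0(prefix[bad], anchor, spacer[bad], suffix[bad])
    }
    if (any(regexpr(anchor, reads, fixed = TRUE) != layout$offset + 1L))
      stop("could not place anchor unambiguously; use a longer anchor")
  }
  reads
}

#' Count sgRNA spacers in a FASTQ file
#'
#' Extracts the putative 20-mer from each read according to `layout` and
#' assigns the read to a guide only on an exact match to that guide's
#' spacer; every other read (mismatch, missing anchor, short read) counts
#' as unassigned. Assigned plus unassigned always equals the number of
#' records in the file, and counts do not depend on read order.
#'
#' @param fastq_path Path to a FASTQ file (gzip-compressed accepted).
#' @param library The `sgrna_library` to count against.
#' @param layout A [fastq_layout()] describing where the spacer sits.
#' @param revcomp If `TRUE`, reads are reverse-complemented before
#'   extraction (for libraries sequenced on the opposite strand).
#' @return A list of class `spacer_counts`: `counts` (data frame
#'   `guide_id`, `count` over the full library), `unassigned`, `total`.
#' @export
count_spacers <- function(fastq_path, library, layout = fastq_layout(),
                          revcomp = FALSE) {
  stopifnot(inherits(library, "sgrna_library"),
            inherits(layout, "fastq_layout"))
  if (!file.exists(fastq_path)) stop("FASTQ file not found: ", fastq_path)
  reads <- tryCatch(
    as.character(Biostrings::readDNAStringSet(fastq_path, format = "fastq")),
    error = function(e) {
      if (fastq_is_empty(fastq_path)) return(character(0))
      stop("failed to read FASTQ ", fastq_path, ": ", conditionMessage(e))
    })
  if (revcomp && length(reads))
    reads <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(reads)))
  k <- layout$spacer_length
  if (is.null(layout$anchor)) {
    start <- rep(layout$offset + 1L, length(reads))
  } else {
    pos <- regexpr(layout$anchor, reads, fixed = TRUE)
    start <- ifelse(pos > 0L, pos + nchar(layout$anchor), NA_integer_)
  }
  extracted <- substr(reads, start, start + k - 1L)
  extracted[is.na(start) | nchar(extracted) < k] <- NA_character_
  idx <- match(extracted, library$spacer)
  counts <- tabulate(idx, nbins = nrow(library))
  unassigned <- sum(is.na(idx))
  structure(list(counts = data.frame(guide_id = library$guide_id,
                                     count = counts,
                                     stringsAsFactors = FALSE),
                 unassigned = unassigned,
                 total = length(reads)),
            class = "spacer_counts")
}

fastq_is_empty <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  length(readLines(con, n = 1L)) == 0L
}

#' @export
print.spacer_counts <- function(x, ...) {
  cat("spacer counts:", x$total, "reads,", x$total - x$unassigned,
      "assigned,", x$unassigned, "unassigned\n")
  invisible(x)
}
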