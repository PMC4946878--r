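#' Construct and validate an sgRNA library
#'
#' An sgRNA library maps guide identifiers to their 20-nt spacer sequences
#' and target gene symbols; it defines the measurement universe of a pooled
#' screen (GeCKO-v2-style libraries carry at least six guides per gene).
#'
#' @param guide_id Character vector of unique guide identifiers.
#' @param spacer Character vector of spacer sequences; must be unique across
#'   the library, of one common length (20 by default) and drawn from the
#'   ACGT alphabet.
#' @param gene Character vector of target gene symbols, one per guide.
#' @param spacer_length Required spacer length in nucleotides.
#'
#' @return A data frame of class `sgrna_library` with columns `guide_id`,
#'   `spacer`, `gene`.
#' @examples
#' lib <- sgrna_library(c("g1", "g2"),
#'                      c(strrep("A", 20), strrep("C", 20)),
#'                      c("TP53", "TP53"))
#' @export
sgrna_library <- function(guide_id, spacer, gene, spacer_length = 20L) {
  guide_id <- as.character(guide_id)
  spacer <- toupper(as.character(spacer))
  gene <- as.character(gene)
  if (length(guide_id) == 0L) stop("library must contain at least one guide")
  if (length(spacer) != length(guide_id) || length(gene) != length(guide_id))
    stop("guide_id, spacer and gene must have equal length")
  if (anyDuplicated(guide_id))
    stop("duplicate guide_id: ",
         paste(unique(guide_id[duplicated(guide_id)]), collapse = ", "))
  if (anyDuplicated(spacer))
    stop("duplicate spacer sequences: ",
         paste(unique(spacer[duplicated(spacer)]), collapse = ", "))
  bad_len <- nchar(spacer) != spacer_length
  if (any(bad_len))
    stop("spacers must be ", spacer_length, " nt; offending guides: ",
         paste(guide_id[bad_len], collapse = ", "))
  bad_alpha <- grepl("[^ACGT]", spacer)
  if (any(bad_alpha))
    stop("spacers must contain only A/C/G/T; offending guides: ",
         paste(guide_id[bad_alpha], collapse = ", "))
  out <- data.frame(guide_id = guide_id, spacer = spacer, gene = gene,
                    stringsAsFactors = FALSE)
  class(out) <- c("sgrna_library", "data.frame")
  out
}

#' @export
print.sgrna_library <- function(x, ...) {
  cat("sgRNA library:", nrow(x), "guides targeting",
      length(unique(x$gene)), "genes\n")
  print.data.frame(head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more guides\n")
  invisible(x)
}

#' Read or write an sgRNA library TSV
#'
#' The file format is tab-delimited UTF-8 with the header
#' `guide_id<TAB>spacer<TAB>gene`. Reading validates the same invariants as
#' [sgrna_library()] and reports the 1-based file line of a malformed row.
#'
#' @param path Path to the TSV file.
#' @return `read_library()` returns an `sgrna_library`; `write_library()`
#'   returns `path` invisibly.
#' @seealso [sgrna_library()]
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", quote = "",
                    stringsAsFactors = FALSE)
  required <- c("guide_id", "spacer", "gene")
  if (!identical(names(raw)[seq_along(required)], required))
    stop("library header must be 'guide_id\\tspacer\\tgene'; found: ",
         paste(names(raw), collapse = ", "))
  bad <- which(is.na(raw$guide_id) | raw$guide_id == "" |
                 is.na(raw$spacer) | raw$spacer == "" |
                 is.na(raw$gene) | raw$gene == "")
  if (length(bad))
    stop("malformed library row at line ", bad[1L] + 1L,
         " of ", path, " (empty or missing field)")
  sgrna_library(raw$guide_id, raw$spacer, raw$gene)
}

#' @param library An `sgrna_library`.
#' @rdname read_library
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "sgrna_library"))
  write.table(as.data.frame(library)[, c("guide_id", "spacer", "gene")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

# Number of guides per gene, as a named integer vector.
guides_per_gene <- function(library) {
  tab <- table(library$gene)
  setNames(as.integer(tab), names(tab))
}
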