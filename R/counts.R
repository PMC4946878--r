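#' Construct and validate a screen count table
#'
#' A screen count table holds, for every screen of an experiment and every
#' guide of the companion library, the integer read count in the baseline
#' sample (harvested shortly after selection onset, capturing the
#' pre-selection sgRNA distribution) and in the survivor sample (after the
#' selection period). The long format carries all screens in one table; the
#' guide set must be identical across screens.
#'
#' @param x A data frame with columns `screen_id`, `guide_id`,
#'   `baseline_count`, `survivor_count`.
#' @param library Optional `sgrna_library`; when supplied, every `guide_id`
#'   must exist in it and every screen must cover the full library.
#'
#' @return A data frame of class `screen_counts`.
#' @export
screen_counts <- function(x, library = NULL) {
  required <- c("screen_id", "guide_id", "baseline_count", "survivor_count")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("count table lacks columns: ", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x)[required]
  x$screen_id <- as.character(x$screen_id)
  x$guide_id <- as.character(x$guide_id)
  for (col in c("baseline_count", "survivor_count")) {
    v <- x[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != floor(v)))
      stop(col, " must be non-negative integers")
    x[[col]] <- as.integer(round(v))
  }
  split_guides <- split(x$guide_id, x$screen_id)
  ref <- sort(split_guides[[1L]])
  for (s in names(split_guides)) {
    g <- split_guides[[s]]
    if (anyDuplicated(g))
      stop("screen ", s, " lists duplicated guide_ids")
    if (!identical(sort(g), ref))
      stop("guide set differs between screens (", names(split_guides)[1L],
           " vs ", s, ")")
  }
  if (!is.null(library)) {
    unknown <- setdiff(x$guide_id, library$guide_id)
    if (length(unknown))
      stop("guide_ids absent from library: ",
           paste(unknown, collapse = ", "))
  }
  rownames(x) <- NULL
  class(x) <- c("screen_counts", "data.frame")
  x
}

#' @export
print.screen_counts <- function(x, ...) {
  cat("screen counts:", length(unique(x$screen_id)), "screens x",
      length(unique(x$guide_id)), "guides\n")
  print.data.frame(head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Read or write screen count tables
#'
#' Tab-delimited files with header
#' `screen_id<TAB>guide_id<TAB>baseline_count<TAB>survivor_count`.
#' On reading, guides of the library missing from a screen are filled in
#' with zero counts (with a warning); guide IDs not present in the library
#' and negative or non-integer counts are validation errors.
#'
#' @param path Path to the TSV file.
#' @param library The companion `sgrna_library`.
#' @return `read_counts()` returns a `screen_counts` table covering the full
#'   library in every screen; `write_counts()` returns `path` invisibly.
#' @export
read_counts <- function(path, library) {
  if (!file.exists(path)) stop("count file not found: ", path)
  stopifnot(inherits(library, "sgrna_library"))
  raw <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
  required <- c("screen_id", "guide_id", "baseline_count", "survivor_count")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("count file lacks columns: ", paste(missing_cols, collapse = ", "))
  unknown <- setdiff(raw$guide_id, library$guide_id)
  if (length(unknown))
    stop("guide_ids not in library: ", paste(unknown, collapse = ", "))
  for (col in c("baseline_count", "survivor_count")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v) || any(v < 0) || any(v != floor(v)))
      stop(col, " must be non-negative integers in ", path)
  }
  screens <- unique(as.character(raw$screen_id))
  full <- expand.grid(guide_id = library$guide_id, screen_id = screens,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  merged <- merge(full, raw, by = c("screen_id", "guide_id"),
                  all.x = TRUE, sort = FALSE)
  n_missing <- sum(is.na(merged$baseline_count) | is.na(merged$survivor_count))
  if (n_missing > 0L) {
    warning(n_missing, " guide/screen entries absent from ", path,
            "; filled with zero counts")
    merged$baseline_count[is.na(merged$baseline_count)] <- 0L
    merged$survivor_count[is.na(merged$survivor_count)] <- 0L
  }
  merged <- merged[order(match(merged$screen_id, screens),
                         match(merged$guide_id, library$guide_id)), ]
  screen_counts(merged, library)
}

#' @param counts A `screen_counts` table.
#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "screen_counts"))
  write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
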