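#' Construct and validate a study design
#'
#' A study design maps each sample to its plot, block, treatment and
#' sampling day. Plots are the whole-plot units of a randomized complete
#' block design: every plot belongs to exactly one block and carries
#' exactly one treatment for the duration of the experiment, and each
#' plot is sampled at most once per day.
#'
#' @param x data.frame with columns `sample_id`, `plot`, `block`,
#'   `treatment` (one of `"control"`, `"novel"`, `"repeated"`) and `day`
#'   (non-negative integer days post-disturbance).
#' @return A `study_design`: the validated data.frame (character ids,
#'   integer days) with attribute `complete` indicating whether every
#'   block holds one plot per treatment and every plot was sampled on
#'   every day observed anywhere in the design.
#' @export
study_design <- function(x) {
  req <- c("sample_id", "plot", "block", "treatment", "day")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0L)
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "))
  d <- data.frame(
    sample_id = as.character(x$sample_id),
    plot      = as.character(x$plot),
    block     = as.character(x$block),
    treatment = as.character(x$treatment),
    day       = x$day,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(d$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  bad_trt <- setdiff(unique(d$treatment), valid_treatments())
  if (length(bad_trt) > 0L)
    stop("unknown treatment label(s): ", paste(bad_trt, collapse = ", "),
         " (expected ", paste(valid_treatments(), collapse = "/"), ")")
  if (!is.numeric(d$day) || any(is.na(d$day)) || any(d$day < 0) ||
      any(d$day != round(d$day)))
    stop("day must be a nonnegative integer")
  d$day <- as.integer(d$day)

  ## every plot maps to exactly one block and one treatment
  pb <- unique(d[, c("plot", "block")])
  if (anyDuplicated(pb$plot))
    stop("design error: plot(s) assigned to more than one block: ",
         paste(unique(pb$plot[duplicated(pb$plot)]), collapse = ", "))
  pt <- unique(d[, c("plot", "treatment")])
  if (anyDuplicated(pt$plot))
    stop("design error: plot(s) assigned to more than one treatment: ",
         paste(unique(pt$plot[duplicated(pt$plot)]), collapse = ", "))
  if (anyDuplicated(d[, c("plot", "day")]))
    stop("design error: more than one sample for some (plot, day) pair")

  ## completeness: one plot per treatment per block, all plots on all days
  tab <- table(pb$block, pt$treatment[match(pb$plot, pt$plot)])
  blocks_complete <- all(tab == 1L) &&
    ncol(tab) == length(valid_treatments())
  days_all <- sort(unique(d$day))
  sampling_complete <- all(table(factor(d$plot), factor(d$day, levels = days_all)) == 1L)
  structure(d, class = c("study_design", "data.frame"),
            complete = blocks_complete && sampling_complete)
}

valid_treatments <- function() c("control", "novel", "repeated")

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %d samples, %d plots, %d blocks, %d days%s\n",
              nrow(x), length(unique(x$plot)), length(unique(x$block)),
              length(unique(x$day)),
              if (isTRUE(attr(x, "complete"))) "" else " [incomplete]"))
  invisible(x)
}

#' Read sample metadata into a study design
#'
#' @param path tab-separated file with a header row and columns
#'   `sample_id`, `plot`, `block`, `treatment`, `day`.
#' @return a validated [study_design()].
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  study_design(x)
}

#' Write a study design to TSV
#' @param design a [study_design()]
#' @param path output file
#' @export
write_metadata <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a count table
#'
#' Samples are rows, taxa are columns; entries are nonnegative integer
#' read counts. Row and column names are the sample and taxon ids.
#'
#' @param mat numeric matrix with rownames (sample ids) and colnames
#'   (taxon ids)
#' @return integer matrix of class `count_table`
#' @export
count_table <- function(mat) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("count table needs sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(mat)))
    stop("duplicated sample id(s): ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  if (anyDuplicated(colnames(mat)))
    stop("duplicated taxon id(s): ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  if (any(is.na(mat))) stop("count table contains missing values")
  if (any(mat < 0)) stop("count table contains negative values")
  if (any(mat != round(mat))) stop("count table contains non-integer values")
  storage.mode(mat) <- "integer"
  structure(mat, class = c("count_table", "matrix", "array"))
}

#' Read a feature table
#'
#' @param path path to the table
#' @param format `"tsv"` (tab-separated, header row, first column sample
#'   or taxon ids) or `"biom-json"` (BIOM 1.0 JSON)
#' @param orientation for TSV input: `"samples_as_rows"` or
#'   `"taxa_as_rows"`. There is no guessing; the caller must declare the
#'   orientation. BIOM files carry their own orientation (rows are
#'   observations/taxa).
#' @return a [count_table()] with samples as rows
#' @export
read_count_table <- function(path, format = c("tsv", "biom-json"),
                             orientation = c("samples_as_rows", "taxa_as_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("feature table not found: ", path)
  if (format == "tsv") {
    x <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                           stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(x[[1L]])
    m <- as.matrix(x[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!vapply(x[-1L], is.numeric, logical(1)))[1L]
      stop("non-numeric counts in column '", names(x)[-1L][bad], "'")
    }
    rownames(m) <- ids
    if (orientation == "taxa_as_rows") m <- t(m)
  } else {
    b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(b$rows) || is.null(b$columns) || is.null(b$data))
      stop("malformed BIOM-JSON: missing rows/columns/data")
    taxa <- vapply(b$rows, function(r) r$id, character(1))
    samples <- vapply(b$columns, function(r) r$id, character(1))
    m <- matrix(0, length(taxa), length(samples),
                dimnames = list(taxa, samples))
    if (identical(b$matrix_type, "sparse")) {
      for (trip in b$data) {
        m[trip[[1L]] + 1L, trip[[2L]] + 1L] <- trip[[3L]]
      }
    } else {
      for (i in seq_along(b$data)) m[i, ] <- unlist(b$data[[i]])
    }
    m <- t(m)  # BIOM rows are taxa; we use samples as rows
  }
  count_table(m)
}

#' Write a count table as TSV (samples as rows)
#' @param table a [count_table()]
#' @param path output file
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy a count table to even depth
#'
#' Each sample is subsampled without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Samples with fewer than
#' `depth` total reads are dropped and reported via the `"dropped"`
#' attribute; dropping (rather than padding) changes downstream degrees
#' of freedom, so callers should inspect that attribute.
#'
#' @param table a [count_table()]
#' @param depth target reads per sample (the study default is 5500)
#' @param seed integer seed making the draw reproducible
#' @return rarefied [count_table()] with attribute `dropped` (character
#'   vector of removed sample ids)
#' @export
rarefy <- function(table, depth = 5500, seed = 1L) {
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1)
    stop("depth must be a positive integer")
  depth <- as.integer(depth)
  totals <- rowSums(table)
  keep <- totals >= depth
  dropped <- rownames(table)[!keep]
  if (length(dropped) > 0L)
    message("rarefy: dropped ", length(dropped), " sample(s) below depth ",
            depth, ": ", paste(dropped, collapse = ", "))
  if (!any(keep)) stop("no sample reaches rarefaction depth ", depth)
  kept <- table[keep, , drop = FALSE]
  out <- withr::with_seed(as.integer(seed), {
    t(apply(kept, 1L, function(counts) {
      n <- sum(counts)
      if (n == depth) return(as.integer(counts))
      ## draw `depth` read positions among n without replacement and
      ## bin them back into taxa
      pos <- sample.int(n, depth)
      upper <- cumsum(counts)
      tabulate(findInterval(pos, c(0L, upper), left.open = TRUE),
               nbins = length(counts))
    }))
  })
  colnames(out) <- colnames(table)
  res <- count_table(out)
  attr(res, "dropped") <- dropped
  res
}

#' Remove singleton taxa
#'
#' Taxa whose total count across all retained samples is exactly one are
#' removed. All-zero taxa are dropped by default (`drop_empty = TRUE`).
#'
#' @param table a [count_table()]
#' @param drop_empty drop taxa with zero total count as well
#' @return filtered [count_table()]
#' @export
remove_singletons <- function(table, drop_empty = TRUE) {
  tot <- colSums(table)
  keep <- tot != 1L & (!drop_empty | tot > 0L)
  res <- count_table(table[, keep, drop = FALSE])
  attr(res, "removed") <- colnames(table)[!keep]
  res
}

#' Convert counts to relative abundance
#'
#' Each sample (row) is divided by its total. Zero-total samples become
#' zero rows and trigger a warning.
#'
#' @param table a [count_table()] or numeric matrix
#' @return matrix of class `rel_abundance_table` with rows summing to 1
#'   (or 0 for empty samples)
#' @export
to_relative_abundance <- function(table) {
  m <- unclass(table)
  storage.mode(m) <- "double"
  tot <- rowSums(m)
  if (any(tot == 0))
    warning("zero-total sample(s) left as zero rows: ",
            paste(rownames(m)[tot == 0], collapse = ", "))
  nz <- tot > 0
  m[nz, ] <- m[nz, , drop = FALSE] / tot[nz]
  structure(m, class = c("rel_abundance_table", "matrix", "array"))
}
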