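# Shared fixtures: tiny designs and tables built in code.

# blocked design: n_blocks blocks x one plot per treatment x days
make_design <- function(n_blocks = 2L, days = c(0L, 1L, 3L),
                        treatments = c("control", "novel", "repeated")) {
  plots <- as.vector(outer(treatments, sprintf("B%d", seq_len(n_blocks)),
                           function(t, b) paste0(b, "_", t)))
  blk <- rep(sprintf("B%d", seq_len(n_blocks)), each = length(treatments))
  trt <- rep(treatments, times = n_blocks)
  df <- expand.grid(day = days, plot = plots, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$block <- blk[match(df$plot, plots)]
  df$treatment <- trt[match(df$plot, plots)]
  df$sample_id <- paste0(df$plot, "_d", df$day)
  study_design(df[, c("sample_id", "plot", "block", "treatment", "day")])
}

random_counts <- function(design, n_taxa = 20L, lambda = 50, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(rpois(nrow(design) * n_taxa, lambda), nrow(design), n_taxa,
                dimnames = list(design$sample_id,
                                sprintf("ASV%03d", seq_len(n_taxa))))
    count_table(m)
  })
}

euclid_dist <- function(points, ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(points)))
  m <- as.matrix(dist(points))
  dimnames(m) <- list(ids, ids)
  dist_matrix(m, metric = "euclidean")
}

# reference Bray-Curtis by the definition, one pair at a time
bray_ref <- function(x, y) sum(abs(x - y)) / sum(x + y)
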