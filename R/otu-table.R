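#' Construct an OTU count table
#'
#' The universal input object of the package: a samples x taxa matrix of
#' non-negative integer read counts with unique sample and taxon identifiers
#' and an optional per-taxon domain tag (`"bacteria"`, `"fungi"` or
#' `"unknown"`).
#'
#' @param counts numeric matrix, samples in rows, taxa in columns, with
#'   dimnames. All entries must be non-negative integers.
#' @param domain optional character vector of per-taxon domain tags, recycled
#'   to the number of taxa. Defaults to `"unknown"`.
#' @return an object of class `otu_table`: the validated integer matrix with a
#'   `domain` attribute.
#' @export
otu_table <- function(counts, domain = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon ids")
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(is.na(counts))) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("counts must be integers")
  storage.mode(counts) <- "double"
  if (is.null(domain)) domain <- "unknown"
  domain <- rep_len(as.character(domain), ncol(counts))
  if (!all(domain %in% c("bacteria", "fungi", "unknown")))
    stop("domain tags must be 'bacteria', 'fungi' or 'unknown'")
  structure(counts, domain = domain, class = c("otu_table", "matrix"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d taxa, %s reads total\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  dom <- table(attr(x, "domain"))
  cat("domains:", paste(names(dom), dom, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

domain_tags <- function(x) attr(x, "domain")

keep_taxa <- function(x, keep) {
  if (!any(keep)) stop("filter removed all taxa")
  otu_table(unclass(x)[, keep, drop = FALSE], domain = domain_tags(x)[keep])
}

#' Read an OTU table from a dense TSV file
#'
#' @param path path to a tab-separated file with a header row; the first
#'   column holds identifiers.
#' @param orientation `"samples"` if samples are rows, `"taxa"` if taxa are
#'   rows (the file is transposed to samples x taxa).
#' @param domain optional per-taxon domain tags (after transposition).
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path, orientation = c("samples", "taxa"),
                           domain = NULL) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in OTU table")
  rownames(m) <- ids
  if (orientation == "taxa") m <- t(m)
  otu_table(m, domain = domain)
}

#' Write an OTU table as dense TSV (samples as rows)
#'
#' @param x an [otu_table()]
#' @param path output path
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file or string
#'
#' Thin wrapper around [ape::read.tree()] that validates tip labels and
#' branch lengths so downstream cophenetic distances are well defined.
#'
#' @param path path to a Newick file, or a literal Newick string
#'   (`text = TRUE` semantics are auto-detected from a trailing `";"`).
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- if (grepl(";[[:space:]]*$", path)) ape::read.tree(text = path)
        else ape::read.tree(path)
  if (is.null(tr)) stop("malformed Newick input")
  if (is.null(tr$tip.label) || anyDuplicated(tr$tip.label))
    stop("tips must be uniquely labeled")
  if (is.null(tr$edge.length)) stop("branch lengths are required")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  tr
}

#' Drop taxa with fewer than `min_total` reads across all samples
#'
#' Removes low-count taxa likely to reflect PCR/sequencing error. The bound is
#' strict: a taxon totalling exactly `min_total` reads is kept.
#'
#' @param x an [otu_table()]
#' @param min_total minimum total read count, default 10
#' @export
filter_min_total_count <- function(x, min_total = 10) {
  stopifnot(min_total >= 1)
  keep_taxa(x, colSums(x) >= min_total)
}

#' Drop taxa rarer than a relative-abundance cutoff
#'
#' A taxon is removed when its share of the grand total read count across all
#' samples falls strictly below `min_rel` (default 0.01%), mitigating zero
#' inflation before network inference.
#'
#' @param x an [otu_table()]
#' @param min_rel minimum overall relative abundance, default `1e-4`
#' @export
filter_rare_relative <- function(x, min_rel = 1e-4) {
  if (sum(x) == 0) stop("empty table")
  keep_taxa(x, colSums(x) / sum(x) >= min_rel)
}

#' Rarefy each sample to a fixed read depth
#'
#' Subsamples reads without replacement (multivariate hypergeometric) so every
#' sample sums exactly to `depth`. Reproducible under `seed`.
#'
#' @param x an [otu_table()]
#' @param depth target reads per sample; every sample total must be >= depth
#' @param seed integer seed
#' @export
rarefy <- function(x, depth, seed) {
  tot <- rowSums(x)
  if (any(tot < depth)) {
    bad <- rownames(x)[which(tot < depth)[1]]
    stop(sprintf("sample '%s' has %d reads, fewer than depth %d",
                 bad, tot[bad], depth))
  }
  set.seed(seed)
  m <- unclass(x)
  storage.mode(m) <- "integer"
  r <- vegan::rrarefy(m, depth)
  otu_table(r, domain = domain_tags(x))
}

#' Convert counts to within-sample relative abundances
#'
#' @param x an [otu_table()]
#' @return numeric matrix, rows summing to 1, with a `domain` attribute.
#' @export
to_relative_abundance <- function(x) {
  tot <- rowSums(x)
  if (any(tot == 0)) stop("empty sample(s): ",
                          paste(rownames(x)[tot == 0], collapse = ", "))
  f <- sweep(unclass(x), 1, tot, "/")
  attr(f, "domain") <- domain_tags(x)
  f
}

#' Write an analysis result to disk
#'
#' @param obj a data.frame, matrix, list, or [igraph::graph] object
#' @param path output file path
#' @param format one of `"tsv"`, `"json"`, `"graphml"`, `"edge-list"`
#' @export
write_results <- function(obj, path, format = c("tsv", "json", "graphml",
                                                "edge-list")) {
  format <- match.arg(format)
  switch(format,
    tsv = {
      df <- if (is.matrix(obj))
        data.frame(id = rownames(obj), obj, check.names = FALSE)
      else as.data.frame(obj)
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    json = jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    graphml = igraph::write_graph(obj, path, format = "graphml"),
    `edge-list` = {
      el <- igraph::as_data_frame(obj, what = "edges")
      utils::write.table(el, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  invisible(path)
}
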