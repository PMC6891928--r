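#' Construct an OTU table
#'
#' An OTU table holds abundances of taxa (rows) across samples (columns),
#' either as read counts (`mode = "counts"`) or as per-sample relative
#' abundances summing to one (`mode = "relative"`). It is the substrate of
#' every analysis in the package.
#'
#' @param counts numeric matrix, taxa x samples, with unique row and column
#'   names (OTU ids and sample ids). All values must be non-negative.
#' @param mode `"counts"` or `"relative"`.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (the matrix) and `mode`.
#' @examples
#' m <- matrix(c(5, 3, 0, 0, 2, 7), nrow = 3,
#'             dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
#' tab <- otu_table(m)
#' to_relative(tab)
#' @export
otu_table <- function(counts, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have OTU ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) stop("`counts` contains missing values")
  if (any(counts < 0)) stop("`counts` contains negative values")
  storage.mode(counts) <- "double"
  if (mode == "relative") {
    cs <- colSums(counts)
    bad <- colnames(counts)[abs(cs - 1) > 1e-9]
    if (length(bad))
      stop("relative-mode columns must sum to 1: ", paste(bad, collapse = ", "))
  }
  structure(list(counts = counts, mode = mode), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d taxa x %d samples (%s mode)\n",
              nrow(x$counts), ncol(x$counts), x$mode))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

otu_ids <- function(table) rownames(table$counts)
sample_ids <- function(table) colnames(table$counts)

stopifnot_counts <- function(table, what) {
  if (!inherits(table, "otu_table")) stop(what, " requires an `otu_table`")
  if (table$mode != "counts") stop(what, " is defined on counts-mode tables")
}

#' Read an OTU table from TSV or BIOM
#'
#' The TSV dialect is QIIME-classic style: first column OTU id (header
#' optionally `#OTU ID`), remaining columns one per sample, tab-separated.
#' BIOM files are read via the biomformat package (JSON BIOM v1).
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @return A counts-mode [otu_table()] with row/column order as in the file.
#' @examples
#' f <- system.file("extdata", "example_otu_table.tsv", package = "mgxdiff")
#' read_otu_table(f)
#' @export
read_otu_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(otu_table(m, mode = "counts"))
  }
  lines <- readLines(path)
  if (!length(lines)) stop("parse error in ", path, ": empty file")
  df <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("parse error in ", path, ": need id column plus samples")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    num <- suppressWarnings(as.numeric(m))
    bad <- which(is.na(num) & !is.na(m))[1]
    stop("parse error in ", path, ": non-numeric value at data row ",
         (bad - 1) %% nrow(m) + 1, ", column ",
         colnames(m)[(bad - 1) %/% nrow(m) + 1])
  }
  rownames(m) <- ids
  otu_table(m, mode = "counts")
}

#' Write an OTU table as TSV
#'
#' Writes the QIIME-classic dialect read by [read_otu_table()] (`#OTU ID`
#' header, tab separation). Values are written in full precision.
#'
#' @param table an [otu_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  m <- table$counts
  header <- paste(c("#OTU ID", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], format(m[i, ], digits = 17, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' @param table a counts-mode [otu_table()] where every sample has a
#'   positive total.
#' @return A relative-mode table; each column divided by its sum.
#' @export
to_relative <- function(table) {
  stopifnot_counts(table, "to_relative")
  cs <- colSums(table$counts)
  if (any(cs <= 0))
    stop("samples with zero total reads: ",
         paste(colnames(table$counts)[cs <= 0], collapse = ", "))
  otu_table(sweep(table$counts, 2, cs, "/"), mode = "relative")
}

#' Filter taxa by total read count
#'
#' Removes taxa whose total reads across all samples fall below
#' `min_reads`; taxa at the boundary are kept. The default of 80 reads
#' removes approximate singletons (about one read per subject in a typical
#' cohort of that size) ahead of network construction.
#'
#' @param table counts-mode [otu_table()].
#' @param min_reads minimum row-sum to retain a taxon.
#' @return Table restricted to taxa with row-sum `>= min_reads`; the sample
#'   set is unchanged. Can legitimately return a 0-taxon table.
#' @export
filter_min_total <- function(table, min_reads = 80) {
  stopifnot_counts(table, "filter_min_total")
  keep <- rowSums(table$counts) >= min_reads
  out <- table
  out$counts <- table$counts[keep, , drop = FALSE]
  out
}

#' Read sample metadata
#'
#' Expects a TSV with at least the columns `sample_id`, `subject_id`, plus
#' any grouping columns (for example `sex`, `body_site`).
#'
#' @param path TSV path.
#' @return data.frame with character columns; `sample_id` values unique.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "subject_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df
}

#' Read a taxonomy map
#'
#' Two-column TSV `otu_id`, `lineage` with `;`-separated ranks
#' (Greengenes-style `k__...; p__...; ...` prefixes are recognised).
#'
#' @param path TSV path.
#' @return Named character vector: lineage string per OTU id.
#' @export
read_taxonomy_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("taxonomy file needs otu_id and lineage columns")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Extract the phylum rank from lineage strings
#'
#' Total over inputs: OTUs with no recognisable phylum rank (missing from
#' the map, empty rank, or bare `p__`) map to `"Unknown"`.
#'
#' @param taxonomy named character vector as from [read_taxonomy_map()].
#' @param ids OTU ids to look up (default: all in `taxonomy`).
#' @return Named character vector of phylum labels.
#' @export
phylum_of <- function(taxonomy, ids = names(taxonomy)) {
  out <- vapply(ids, function(id) {
    lin <- unname(taxonomy[id])
    if (is.na(lin)) return("Unknown")
    ranks <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    hit <- ranks[startsWith(ranks, "p__")]
    ph <- if (length(hit)) sub("^p__", "", hit[1]) else if (length(ranks) >= 2) ranks[2] else ""
    if (!nzchar(ph)) "Unknown" else ph
  }, character(1))
  stats::setNames(out, ids)
}

#' Split an OTU table into two group-specific tables
#'
#' Restricts to the samples of one body site and partitions them by a
#' two-valued grouping column (for example `sex`). Taxa rows are kept
#' identical in both outputs so downstream shared-species analyses can
#' rely on row alignment.
#'
#' @param table an [otu_table()].
#' @param metadata data.frame as from [read_sample_metadata()].
#' @param site body-site label to select, or `NULL` to use all samples.
#' @param group_field name of the two-valued grouping column.
#' @param site_field name of the body-site column.
#' @return Named list of two tables, one per group value (sorted order).
#' @export
split_by_group <- function(table, metadata, site = NULL,
                           group_field = "sex", site_field = "body_site") {
  stopifnot(inherits(table, "otu_table"))
  sids <- sample_ids(table)
  missing_md <- setdiff(sids, metadata$sample_id)
  if (length(missing_md))
    stop("samples absent from metadata: ", paste(missing_md, collapse = ", "))
  md <- metadata[match(sids, metadata$sample_id), , drop = FALSE]
  if (!is.null(site)) {
    if (!site_field %in% names(md)) stop("metadata has no column ", site_field)
    keep <- md[[site_field]] == site
    md <- md[keep, , drop = FALSE]
    sids <- sids[keep]
    if (!length(sids)) stop("no samples at site ", site)
  }
  if (!group_field %in% names(md)) stop("metadata has no column ", group_field)
  groups <- md[[group_field]]
  lev <- sort(unique(groups))
  if (length(lev) != 2)
    stop("need exactly two group values, found: ", paste(lev, collapse = ", "))
  out <- lapply(lev, function(g) {
    t2 <- table
    t2$counts <- table$counts[, sids[groups == g], drop = FALSE]
    t2
  })
  stats::setNames(out, lev)
}

#' Rarefy each sample to a common depth
#'
#' Optional pre-step for diversity comparisons: subsamples reads without
#' replacement (via [vegan::rrarefy()]) so every sample has the same
#' depth. Samples below the target depth are dropped with a warning.
#'
#' @param table counts-mode table with integer counts.
#' @param depth target reads per sample.
#' @param seed integer RNG seed.
#' @return Rarefied counts-mode table.
#' @export
rarefy_table <- function(table, depth, seed = 1L) {
  stopifnot_counts(table, "rarefy_table")
  cs <- colSums(table$counts)
  drop <- cs < depth
  if (all(drop)) stop("no sample reaches depth ", depth)
  if (any(drop))
    warning("dropping samples below depth ", depth, ": ",
            paste(colnames(table$counts)[drop], collapse = ", "))
  m <- table$counts[, !drop, drop = FALSE]
  with_seed(seed, {
    r <- suppressWarnings(vegan::rrarefy(t(m), depth))
  })
  otu_table(t(r), mode = "counts")
}
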