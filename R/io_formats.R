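#' @keywords internal
"_PACKAGE"

# -- delimiter handling -------------------------------------------------------

delim_for_path <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

# -- expression matrices ------------------------------------------------------

#' Read a log2 expression matrix
#'
#' Reads a delimited genes-by-samples expression table: first column gene (or
#' probe) identifiers, header row of sample identifiers, numeric cells on the
#' log2 scale. Identifiers are whitespace-stripped and matched case-sensitively.
#'
#' @param path Path to a TSV/CSV file. The delimiter is inferred from the file
#'   extension (`.csv` is comma, anything else tab) unless `delim` is given.
#' @param delim Optional field delimiter overriding the extension rule.
#' @param collapse_map Optional named character vector mapping probe ids to gene
#'   symbols; when supplied the probe-level matrix is collapsed with
#'   [collapse_probes()] before being returned.
#' @return A numeric matrix (genes x samples) with unique rownames (gene ids)
#'   and unique colnames (sample ids); all values finite.
#' @details Duplicate sample ids, duplicate gene ids (unless collapsing is
#'   requested), non-numeric cells and missing values are load errors: relative
#'   expression orderings are ill-defined on imputed data, so nothing is
#'   imputed.
#' @export
read_expression <- function(path, delim = NULL, collapse_map = NULL) {
  sep <- delim_for_path(path, delim)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", comment.char = "",
                           quote = "\"", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression file needs an id column plus >= 1 sample column: ", path)
  gene_ids <- trimws(raw[[1L]])
  sample_ids <- trimws(colnames(raw)[-1L])
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) stop("duplicate sample id(s) in header: ", paste(dup_s, collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or missing expression value at row %d (gene '%s'), column %d (sample '%s')",
                 bad[1L, 1L], gene_ids[bad[1L, 1L]], bad[1L, 2L], sample_ids[bad[1L, 2L]]))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  if (!is.null(collapse_map)) return(collapse_probes(values, collapse_map))
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("duplicate gene id(s): ", paste(utils::head(dup_g, 5L), collapse = ", "),
         " (pass collapse_map to collapse probe-level rows)")
  }
  values
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: values are written with full precision so a
#' read/write round trip is lossless.
#'
#' @param expr Numeric genes-by-samples matrix with dimnames.
#' @param path Output path; delimiter inferred from the extension unless
#'   `delim` is given.
#' @param delim Optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, delim = NULL) {
  check_expression(expr)
  sep <- delim_for_path(path, delim)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_expression <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids in expression matrix")
  if (!all(is.finite(expr))) stop("expression matrix contains non-finite values")
  invisible(expr)
}

#' Collapse probe-level rows to gene level
#'
#' When several probes map to one gene symbol, the gene's row is the arithmetic
#' mean of its probe rows, computed on the provided (log2-scale) values. Probes
#' without a mapping are dropped.
#'
#' @param probe_matrix Numeric probes-by-samples matrix with probe rownames.
#' @param probe_to_gene_map Named character vector: names are probe ids, values
#'   are gene symbols.
#' @return Gene-by-sample matrix with unique gene rownames, genes in
#'   first-appearance order of their probes.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene_map) {
  stopifnot(is.matrix(probe_matrix), is.numeric(probe_matrix))
  if (length(probe_to_gene_map) == 0L) stop("empty probe-to-gene map")
  if (is.null(names(probe_to_gene_map))) stop("probe-to-gene map must be named by probe id")
  map <- stats::setNames(trimws(probe_to_gene_map), trimws(names(probe_to_gene_map)))
  present <- names(map) %in% rownames(probe_matrix)
  if (!all(present)) {
    warning("probe-to-gene map references ", sum(!present),
            " probe(s) absent from the matrix; ignored")
    map <- map[present]
  }
  if (length(map) == 0L) stop("no mapped probes present in the matrix")
  probes <- rownames(probe_matrix)[rownames(probe_matrix) %in% names(map)]
  genes <- map[probes]
  sub <- probe_matrix[probes, , drop = FALSE]
  gene_order <- unique(unname(genes))
  out <- rowsum(sub, group = unname(genes), reorder = FALSE) /
    as.vector(table(factor(genes, levels = unique(unname(genes)))))
  out <- out[gene_order, , drop = FALSE]
  colnames(out) <- colnames(probe_matrix)
  check_expression(out)
}

# -- phenotype tables ---------------------------------------------------------

pheno_columns <- c("sample_id", "response", "dfs_time", "dfs_event",
                   "stage", "age", "gender", "resistance")

#' Normalise a response label vector
#'
#' Response coding is fixed package-wide: the positive class is `"responder"`.
#' Accepts logical, 0/1 numeric, or character/factor labels
#' (`responder`/`non-responder`, case-insensitive, `non_responder` and
#' `nonresponder` also accepted).
#'
#' @param x Vector of labels.
#' @return Character vector of `"responder"` / `"non-responder"` (NA preserved).
#' @export
normalize_response <- function(x) {
  if (is.logical(x)) return(ifelse(x, "responder", "non-responder"))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1) | is.na(x))) stop("numeric response labels must be 0/1")
    return(ifelse(is.na(x), NA_character_, ifelse(x == 1, "responder", "non-responder")))
  }
  v <- tolower(trimws(as.character(x)))
  v <- gsub("[_ ]", "-", v)
  v[v == "nonresponder"] <- "non-responder"
  ok <- v %in% c("responder", "non-responder") | is.na(v)
  if (!all(ok)) stop("unrecognised response label(s): ", paste(unique(v[!ok]), collapse = ", "))
  v
}

#' Read a phenotype table
#'
#' Delimited table with a `sample_id` column and any of: `response` (binary,
#' responder = positive class), `dfs_time` (months), `dfs_event` (0/1),
#' `stage`, `age`, `gender`, `resistance`.
#'
#' @inheritParams read_expression
#' @return data.frame with unique `sample_id`s and normalised `response`.
#' @export
read_phenotype <- function(path, delim = NULL) {
  sep <- delim_for_path(path, delim)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) stop("phenotype table must have a sample_id column")
  df$sample_id <- trimws(as.character(df$sample_id))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s) in phenotype table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if ("response" %in% colnames(df)) df$response <- normalize_response(df$response)
  if ("dfs_time" %in% colnames(df)) {
    if (!"dfs_event" %in% colnames(df))
      stop("dfs_event must be present wherever dfs_time is")
    if (any(df$dfs_time < 0, na.rm = TRUE)) stop("dfs_time must be >= 0")
  }
  df
}

#' Write a phenotype table
#' @param pheno data.frame as returned by [read_phenotype()].
#' @inheritParams write_expression
#' @export
write_phenotype <- function(pheno, path, delim = NULL) {
  sep <- delim_for_path(path, delim)
  utils::write.table(pheno, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- signatures ---------------------------------------------------------------

check_signature <- function(sig) {
  stopifnot(is.data.frame(sig))
  need <- c("rank", "gene_a", "gene_b")
  if (!all(need %in% colnames(sig))) stop("signature needs columns rank, gene_a, gene_b")
  if (nrow(sig) == 0L) stop("empty signature")
  if (!identical(as.integer(sig$rank), seq_len(nrow(sig))))
    stop("signature ranks must be consecutive from 1 in row order")
  if (any(sig$gene_a == sig$gene_b)) stop("signature pair with gene_a == gene_b")
  key <- paste(sig$gene_a, sig$gene_b, sep = "\r")
  if (anyDuplicated(key)) stop("duplicated pair in signature")
  sig
}

#' Read a gene-pair signature
#'
#' Signatures are ordered `(rank, gene_a, gene_b)` rows; the orientation
#' `gene_a > gene_b` (within-sample expression) encodes response. The rank
#' column is optional on input (assigned from row order) but always written.
#'
#' @inheritParams read_expression
#' @return data.frame with columns `rank`, `gene_a`, `gene_b`.
#' @export
read_signature <- function(path, delim = NULL) {
  sep <- delim_for_path(path, delim)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("gene_a", "gene_b") %in% colnames(df)))
    stop("signature file needs gene_a and gene_b columns")
  df$gene_a <- trimws(df$gene_a)
  df$gene_b <- trimws(df$gene_b)
  df$rank <- seq_len(nrow(df))
  check_signature(df[, c("rank", "gene_a", "gene_b")])
}

#' Write a gene-pair signature
#' @param sig Signature data.frame (`rank` optional; assigned by row order).
#' @inheritParams write_expression
#' @export
write_signature <- function(sig, path, delim = NULL) {
  sig$rank <- seq_len(nrow(sig))
  sig <- check_signature(sig[, c("rank", "gene_a", "gene_b")])
  sep <- delim_for_path(path, delim)
  utils::write.table(sig, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# md5 of the packaged fixture, fixed at packaging time
.SIG41_MD5 <- "3a2008b2fecc65c027d7e8c4d3700437"

#' Load the published 41-gene-pair signature
#'
#' Returns the published 41-pair signature for neoadjuvant-chemoradiation
#' response in locally advanced rectal cancer, packaged as a plain-text
#' fixture. For every pair the orientation `gene_a > gene_b` indicates
#' response. The fixture is integrity-checked (md5) at load time.
#'
#' @return Signature data.frame of 41 rows covering 76 unique gene symbols.
#' @export
load_published_signature <- function() {
  path <- system.file("extdata", "signature_41gps.tsv", package = "reopairs",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .SIG41_MD5))
    stop("packaged signature fixture failed its checksum (", sum, ")")
  read_signature(path)
}
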