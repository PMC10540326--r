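# Reading, validating and aligning gene presence/absence matrices and genome
# metadata, and writing per-gene result tables. Orientation convention: Y is
# genes x genomes; X and M are genomes x variables.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a gene presence/absence matrix
#'
#' Two dialects are supported. `"plain"`: a delimited table whose first
#' column holds gene identifiers, remaining columns one genome each, and
#' cells are exactly 0 or 1. `"roary"`: a `gene_presence_absence.csv`-style
#' table where columns before `first_genome_col` are annotation and a
#' non-empty cell in a genome column means the gene is present.
#'
#' @param path Path to a TSV/CSV file (delimiter chosen by extension, or via
#'   `sep`).
#' @param dialect `"plain"` or `"roary"`.
#' @param first_genome_col For the roary dialect, 1-based index of the first
#'   genome column (default 15, the roary layout).
#' @param sep Field delimiter; defaults by file extension.
#' @return List with `gene_ids`, `genome_ids`, and the binary matrix `Y`
#'   (genes x genomes), input order preserved.
#' @export
read_presence_matrix <- function(path, dialect = c("plain", "roary"),
                                 first_genome_col = 15, sep = delim_for(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (dialect == "roary") {
    gene_ids <- raw[[1]]
    gcols <- seq(from = first_genome_col, to = ncol(raw))
    genome_ids <- colnames(raw)[gcols]
    Y <- vapply(gcols, function(j) as.integer(nzchar(trimws(raw[[j]]))),
                integer(nrow(raw)))
    Y <- matrix(Y, nrow = nrow(raw))
  } else {
    gene_ids <- raw[[1]]
    genome_ids <- colnames(raw)[-1]
    Y <- matrix(NA_integer_, nrow(raw), length(genome_ids))
    for (j in seq_along(genome_ids)) {
      v <- trimws(raw[[j + 1]])
      bad <- !(v %in% c("0", "1"))
      if (any(bad)) {
        stop(sprintf(
          "non-binary cell at gene '%s', genome '%s': '%s'",
          gene_ids[which(bad)[1]], genome_ids[j], v[which(bad)[1]]
        ))
      }
      Y[, j] <- as.integer(v)
    }
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(genome_ids)) {
    stop("duplicated genome ids: ",
         paste(unique(genome_ids[duplicated(genome_ids)]), collapse = ", "))
  }
  dimnames(Y) <- list(gene_ids, genome_ids)
  list(gene_ids = gene_ids, genome_ids = genome_ids, Y = Y)
}

#' Write a plain-dialect presence/absence matrix
#'
#' @param Y Binary matrix, genes x genomes.
#' @param gene_ids,genome_ids Row / column identifiers.
#' @param path Output path (TSV/CSV by extension).
#' @export
write_presence_matrix <- function(Y, gene_ids = rownames(Y),
                                  genome_ids = colnames(Y), path) {
  stopifnot(all(Y %in% c(0, 1)))
  df <- data.frame(gene_id = gene_ids, Y, check.names = FALSE)
  colnames(df) <- c("gene_id", genome_ids)
  utils::write.table(df, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# treatment-code a single metadata column; categoricals are coded 0/1 (or
# k-1 dummies) against the lexicographically first level
code_column <- function(v, name) {
  if (anyNA(v) || any(trimws(as.character(v)) == "")) {
    stop("missing values in metadata column '", name,
         "'; no imputation is performed")
  }
  num <- suppressWarnings(as.numeric(v))
  if (!anyNA(num)) {
    out <- matrix(num, ncol = 1, dimnames = list(NULL, name))
    return(out)
  }
  lev <- sort(unique(as.character(v)))
  if (length(lev) == 1) {
    # single-level categorical: a zero contrast column, flagged downstream
    # as a constant covariate
    return(matrix(0, length(v), 1,
                  dimnames = list(NULL, paste0(name, " (constant: ",
                                               lev, ")"))))
  }
  ref <- lev[1]
  cols <- lapply(lev[-1], function(l) as.numeric(v == l))
  out <- do.call(cbind, cols)
  colnames(out) <- paste0(name, "=", lev[-1], " (vs ", ref, ")")
  out
}

#' Read genome metadata and build covariate and quality matrices
#'
#' Reads a delimited per-genome table, codes covariates (numeric columns kept
#' as is, categorical columns treatment-coded against the lexicographically
#' first level, with the coding recorded in the column names), adds a leading
#' all-ones intercept column to `X` unless disabled, and reorders rows to a
#' supplied genome order. Missing values and misaligned genome sets are hard
#' errors.
#'
#' @param path Metadata TSV/CSV.
#' @param genome_id_col Name of the genome identifier column.
#' @param covariate_cols Names of the covariate columns for `X`.
#' @param quality_cols Names of the (numeric) quality columns for `M`.
#' @param genome_order Optional character vector: the genome order of the
#'   presence matrix columns; metadata rows are aligned to it.
#' @param intercept Add a leading all-ones column to `X` (default `TRUE`).
#' @return List with `X` (genomes x p), `M` (genomes x q), `genome_ids`,
#'   `covariate_names`, `quality_names`.
#' @export
read_metadata <- function(path, genome_id_col, covariate_cols, quality_cols,
                          genome_order = NULL, intercept = TRUE,
                          sep = delim_for(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, quote = "\"",
                            comment.char = "", stringsAsFactors = FALSE)
  needed <- c(genome_id_col, covariate_cols, quality_cols)
  absent <- setdiff(needed, colnames(meta))
  if (length(absent)) {
    stop("metadata columns not found: ", paste(absent, collapse = ", "))
  }
  ids <- as.character(meta[[genome_id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicated genome ids in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!is.null(genome_order)) {
    miss_meta <- setdiff(genome_order, ids)
    miss_mat <- setdiff(ids, genome_order)
    if (length(miss_meta) || length(miss_mat)) {
      stop("genome sets do not align; missing from metadata: [",
           paste(miss_meta, collapse = ", "), "]; missing from matrix: [",
           paste(miss_mat, collapse = ", "), "]")
    }
    meta <- meta[match(genome_order, ids), , drop = FALSE]
    ids <- genome_order
  }
  Xl <- lapply(covariate_cols, function(cc) code_column(meta[[cc]], cc))
  X <- do.call(cbind, Xl)
  if (intercept) {
    X <- cbind("(Intercept)" = 1, X)
  }
  Ml <- lapply(quality_cols, function(qc) {
    col <- code_column(meta[[qc]], qc)
    if (ncol(col) != 1 || !is.numeric(col)) {
      stop("quality column '", qc, "' must be numeric")
    }
    col
  })
  M <- do.call(cbind, Ml)
  rownames(X) <- rownames(M) <- ids
  list(X = X, M = M, genome_ids = ids,
       covariate_names = colnames(X), quality_names = colnames(M))
}

#' Assemble and validate a gene presence dataset
#'
#' Bundles the presence matrix with aligned covariates and quality variables,
#' enforcing the container invariants: binary `Y` with no missing values,
#' one `X`/`M` row per genome column of `Y`, unique identifiers.
#'
#' @param Y Binary matrix, genes x genomes.
#' @param X Covariate matrix, genomes x p.
#' @param M Quality matrix or vector, genomes x q.
#' @param gene_ids,genome_ids Identifiers (defaults from dimnames).
#' @return List of class `"gene_presence_dataset"`.
#' @export
gene_presence_dataset <- function(Y, X, M, gene_ids = rownames(Y),
                                  genome_ids = colnames(Y)) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  M <- as.matrix(M)
  if (anyNA(Y) || anyNA(X) || anyNA(M)) stop("missing values are not allowed")
  if (!all(Y %in% c(0, 1))) stop("Y entries must be exactly 0 or 1")
  if (ncol(Y) != nrow(X) || ncol(Y) != nrow(M)) {
    stop("number of genome columns of Y must equal rows of X and M")
  }
  if (!is.null(genome_ids) && anyDuplicated(genome_ids)) {
    stop("genome ids must be unique")
  }
  structure(list(Y = Y, X = X, M = M,
                 gene_ids = gene_ids %||% paste0("gene", seq_len(nrow(Y))),
                 genome_ids = genome_ids %||% paste0("g", seq_len(ncol(Y))),
                 covariate_names = colnames(X), quality_names = colnames(M)),
            class = "gene_presence_dataset")
}

RESULT_COLUMNS <- c("gene_id", "method", "statistic", "p_value", "q_value",
                    "converged_alt", "converged_null", "n_iter_alt",
                    "n_iter_null")

#' Write a per-gene result table
#'
#' Writes a TSV (UTF-8) with the fixed columns `gene_id`, `method`,
#' `statistic`, `p_value`, `q_value`, `converged_alt`, `converged_null`,
#' `n_iter_alt`, `n_iter_null`. Floating-point columns are written with 15
#' significant digits so a read-back reproduces them to at least 12.
#'
#' @param table Data frame with the columns above.
#' @param path Output path.
#' @export
write_results <- function(table, path) {
  stopifnot(nrow(table) > 0, all(RESULT_COLUMNS %in% colnames(table)))
  out <- table[, RESULT_COLUMNS]
  for (cc in c("statistic", "p_value", "q_value")) {
    out[[cc]] <- sprintf("%.15g", out[[cc]])
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
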