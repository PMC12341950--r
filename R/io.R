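#' Read a genetic map from CSV
#'
#' Expects a header with columns `marker`, `chromosome`, `position_cM`.
#' Validation failures name the offending marker.
#'
#' @param path CSV file path.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("marker", "chromosome", "position_cM")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("genetic map file '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pos <- suppressWarnings(as.numeric(df$position_cM))
  if (anyNA(pos) && !anyNA(df$position_cM)) {
    bad <- df$marker[is.na(pos)][1]
    stop("non-numeric position for marker '", bad, "' in '", path, "'")
  }
  df$position_cM <- pos
  genetic_map(df)
}

#' Write a genetic map to CSV
#' @param map a `genetic_map`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  df <- map$markers
  df$position_cM <- fmt_num(df$position_cM)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# numeric formatting convention for all writers: 6 significant digits
fmt_num <- function(x) formatC(x, digits = 6, format = "g")

#' Read a RIL genotype matrix from CSV
#'
#' Rows are lines, columns are markers (first column = line id). Cells hold
#' parental allele codes; the default aliases are `A` (parent 1), `B`
#' (parent 2) and empty/NA for missing. Columns are reordered to match the
#' map; the missing-call fraction is reported via `message()`.
#'
#' @param path CSV file path.
#' @param map the associated [genetic_map()].
#' @param codes named character vector aliasing the on-disk codes, e.g.
#'   `c(A = "BB", B = "SS")` for qtl2-style files.
#' @return character matrix lines x markers with entries `"A"`, `"B"`, `NA`.
#' @export
read_genotypes <- function(path, map, codes = c(A = "A", B = "B")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2) stop("genotype file '", path, "' has no marker columns")
  lines <- df[[1]]
  if (anyDuplicated(lines)) stop("duplicate line id in '", path, "'")
  geno <- as.matrix(df[, -1, drop = FALSE])
  rownames(geno) <- lines
  want <- map$markers$marker
  if (!setequal(colnames(geno), want)) {
    extra <- setdiff(colnames(geno), want)
    miss <- setdiff(want, colnames(geno))
    stop("genotype markers do not match the map",
         if (length(miss)) paste0("; absent from file: ",
                                  paste(utils::head(miss, 5), collapse = ", ")),
         if (length(extra)) paste0("; unknown in map: ",
                                   paste(utils::head(extra, 5), collapse = ", ")))
  }
  geno <- geno[, want, drop = FALSE]
  out <- matrix(NA_character_, nrow(geno), ncol(geno),
                dimnames = dimnames(geno))
  out[geno == codes[["A"]]] <- "A"
  out[geno == codes[["B"]]] <- "B"
  unknown <- !is.na(geno) & geno != "" & geno != "NA" &
    geno != codes[["A"]] & geno != codes[["B"]]
  if (any(unknown)) {
    w <- which(unknown, arr.ind = TRUE)[1, ]
    stop("unknown genotype code '", geno[w[1], w[2]], "' at line '",
         rownames(geno)[w[1]], "', marker '", colnames(geno)[w[2]], "'")
  }
  validate_genotypes(out, map)
  message(sprintf("read_genotypes: %d lines x %d markers, %.2f%% missing",
                  nrow(out), ncol(out), 100 * mean(is.na(out))))
  out
}

#' Write a genotype matrix to CSV
#' @param geno genotype matrix from [read_genotypes()] or
#'   [simulate_ril_genotypes()].
#' @param path output CSV path.
#' @param codes named character vector of on-disk codes (see
#'   [read_genotypes()]).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, codes = c(A = "A", B = "B")) {
  out <- geno
  out[geno == "A"] <- codes[["A"]]
  out[geno == "B"] <- codes[["B"]]
  df <- data.frame(line = rownames(geno), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

validate_genotypes <- function(geno, map) {
  if (ncol(geno) != nrow(map$markers)) {
    stop("genotype matrix has ", ncol(geno), " markers but the map has ",
         nrow(map$markers))
  }
  for (ch in map_chromosomes(map)) {
    cols <- which(map$markers$chromosome == ch)
    all_missing <- rowSums(!is.na(geno[, cols, drop = FALSE])) == 0
    if (any(all_missing)) {
      stop("line '", rownames(geno)[which(all_missing)[1]],
           "' has no genotype call on chromosome '", ch, "'")
    }
  }
  invisible(geno)
}

#' Construct an expression dataset
#'
#' Couples a samples x transcripts abundance matrix with per-sample metadata
#' (genotype id, treatment, replicate). Abundances are treated as
#' already-normalized expression estimates on the scale provided.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   transcripts in columns (colnames = transcript ids).
#' @param meta data.frame with columns `sample`, `genotype`, `treatment`
#'   (in `"control"`/`"SA"`), `replicate`.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, meta) {
  required <- c("sample", "genotype", "treatment", "replicate")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("sample metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  meta <- as.data.frame(meta)[, required]
  meta$sample <- as.character(meta$sample)
  meta$genotype <- as.character(meta$genotype)
  meta$treatment <- as.character(meta$treatment)
  meta$replicate <- as.character(meta$replicate)
  if (anyDuplicated(meta$sample)) {
    stop("duplicate sample id in metadata: ",
         meta$sample[duplicated(meta$sample)][1])
  }
  bad_tr <- setdiff(unique(meta$treatment), c("control", "SA"))
  if (length(bad_tr) > 0) {
    stop("treatment must be 'control' or 'SA'; found: ",
         paste(bad_tr, collapse = ", "))
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs sample rownames and transcript colnames")
  }
  if (anyDuplicated(colnames(values))) stop("transcript ids must be unique")
  no_meta <- setdiff(rownames(values), meta$sample)
  if (length(no_meta) > 0) {
    stop("sample(s) lack metadata: ", paste(utils::head(no_meta, 5),
                                            collapse = ", "))
  }
  no_data <- setdiff(meta$sample, rownames(values))
  if (length(no_data) > 0) {
    stop("metadata sample(s) absent from matrix: ",
         paste(utils::head(no_data, 5), collapse = ", "))
  }
  values <- values[meta$sample, , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$values), "samples x", ncol(x$values),
      "transcripts;", length(unique(x$meta$genotype)), "genotypes,",
      length(unique(x$meta$replicate)), "replicate(s)\n")
  invisible(x)
}

#' Read an expression dataset from TSV files
#'
#' The matrix file holds transcripts in rows and samples in columns (first
#' column = transcript id); metadata holds one row per sample with columns
#' `sample`, `genotype`, `treatment`, `replicate`.
#'
#' @param matrix_path expression matrix TSV.
#' @param metadata_path sample metadata TSV.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(matrix_path, metadata_path) {
  mat <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (anyDuplicated(mat[[1]])) {
    stop("duplicate transcript id in '", matrix_path, "': ",
         mat[[1]][duplicated(mat[[1]])][1])
  }
  values <- t(as.matrix(mat[, -1, drop = FALSE]))
  colnames(values) <- mat[[1]]
  if (!is.numeric(values)) stop("non-numeric expression values in '",
                                matrix_path, "'")
  expression_dataset(values, meta)
}

#' Write an expression dataset to TSV files
#' @param dataset an [expression_dataset()].
#' @param matrix_path output path for the transcripts x samples matrix.
#' @param metadata_path output path for the sample metadata.
#' @return invisibly, `c(matrix_path, metadata_path)`.
#' @export
write_expression <- function(dataset, matrix_path, metadata_path) {
  mat <- t(dataset$values)
  df <- data.frame(transcript = rownames(mat),
                   apply(mat, 2, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("transcript", colnames(mat))
  utils::write.table(df, matrix_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(dataset$meta, metadata_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(matrix_path, metadata_path))
}

#' Read a gene position table
#'
#' @param path TSV with columns `transcript`, `chromosome`, `bp` (physical
#'   position), and optionally `pos_cM` (already-interpolated genetic
#'   position).
#' @return data.frame.
#' @export
read_gene_positions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("transcript", "chromosome")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("gene position file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$transcript <- as.character(df$transcript)
  df$chromosome <- as.character(df$chromosome)
  df
}

#' Read a paralog table
#'
#' @param path TSV with columns `transcript`, `accession`,
#'   `paralog_chromosome`, `paralog_cM` — one row per paralog location of a
#'   transcript's gene family in a given accession.
#' @return data.frame.
#' @export
read_paralogs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("transcript", "accession", "paralog_chromosome", "paralog_cM")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("paralog file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$transcript <- as.character(df$transcript)
  df$accession <- as.character(df$accession)
  df$paralog_chromosome <- as.character(df$paralog_chromosome)
  df
}
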