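# Closed category sets shared by every stage.
GROUPS <- c("CTRL", "MS", "NMOSD", "ITM")
DISEASES <- c("MS", "NMOSD", "ITM")
STATUSES <- c("REMISSION", "RELAPSE", "NONE")
CHEM_CLASSES <- c("sugar", "sugar_alcohol", "amino_acid", "fatty_acid",
                  "organic_acid", "amine", "phosphate", "misc")
CLINICAL_VARS <- c("edss", "ocb", "protein", "wbc", "igg_index")

#' Construct a samples-by-metabolites abundance matrix
#'
#' The central quantitative object of the pipeline: a numeric matrix of
#' relative abundances (GC-MS peak heights or values derived from them) with
#' samples in rows and metabolites in columns. Missing cells (`NA`) encode
#' non-detects; zero is a legitimate measured abundance and is distinct from
#' missing.
#'
#' @param values numeric matrix, samples x metabolites; `NA` marks missing.
#' @param sample_ids,metabolite_ids unique character identifiers; default to
#'   the dimnames of `values`.
#' @return a `metab_matrix`: the matrix with validated dimnames and class.
#' @export
metabolite_matrix <- function(values, sample_ids = rownames(values),
                              metabolite_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(metabolite_ids))
    stop("sample_ids and metabolite_ids are required (or set as dimnames)")
  sample_ids <- as.character(sample_ids)
  metabolite_ids <- as.character(metabolite_ids)
  if (nrow(values) != length(sample_ids))
    stop(sprintf("matrix has %d rows but %d sample ids",
                 nrow(values), length(sample_ids)))
  if (ncol(values) != length(metabolite_ids))
    stop(sprintf("matrix has %d columns but %d metabolite ids",
                 ncol(values), length(metabolite_ids)))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite id: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "))
  neg <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative abundance at sample '%s', metabolite '%s'",
                 sample_ids[neg[1, 1]], metabolite_ids[neg[1, 2]]))
  dimnames(values) <- list(sample_ids, metabolite_ids)
  class(values) <- c("metab_matrix", "matrix", "array")
  values
}

#' @export
print.metab_matrix <- function(x, ...) {
  cat(sprintf("metab_matrix: %d samples x %d metabolites (%d missing cells)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

# Subsetting keeps the class when the result is still a matrix with dimnames.
#' @export
`[.metab_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out) && !is.null(rownames(out)) && !is.null(colnames(out)))
    class(out) <- c("metab_matrix", "matrix", "array")
  out
}

#' Construct and validate a sample annotation table
#'
#' One row per sample: disease group, relapse/remission status and the
#' clinical covariates used by the joint biomarker model. EDSS is the
#' Expanded Disability Status Scale (0-10 in 0.5 steps); OCB the binary
#' oligoclonal-band finding; protein the CSF total protein in mg/dL.
#'
#' @param df data.frame with columns `sample_id`, `group`, `status` and
#'   optionally `edss`, `ocb`, `protein`, `wbc`, `igg_index`,
#'   `pre_treatment`. Missing covariates are `NA`.
#' @return validated data.frame of class `sample_annotation`.
#' @export
sample_annotation <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample annotation lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$group), GROUPS)
  if (length(bad)) stop("unknown group token: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$status), STATUSES)
  if (length(bad)) stop("unknown status token: ", paste(bad, collapse = ", "))
  off <- df$sample_id[df$group == "CTRL" & df$status != "NONE"]
  if (length(off))
    stop("control samples must have status NONE: ", paste(off, collapse = ", "))
  for (v in CLINICAL_VARS)
    if (is.null(df[[v]])) df[[v]] <- NA_real_ else df[[v]] <- as.numeric(df[[v]])
  e <- df$edss[!is.na(df$edss)]
  if (any(e < 0 | e > 10 | abs(e * 2 - round(e * 2)) > 1e-9))
    stop("edss values must lie in 0..10 in 0.5 steps")
  if (any(df$ocb[!is.na(df$ocb)] %in% c(0, 1) == FALSE))
    stop("ocb must be binary (0/1) or missing")
  for (v in c("protein", "wbc", "igg_index")) {
    x <- df[[v]][!is.na(df[[v]])]
    if (any(x < 0)) stop(v, " must be non-negative")
  }
  class(df) <- c("sample_annotation", "data.frame")
  df
}

#' Construct and validate a metabolite annotation table
#'
#' One row per identified metabolite: chemical class (closed vocabulary),
#' binary substructure fingerprint (a `0`/`1` string, one shared length per
#' table), optional external compound identifier, pathway memberships and
#' reaction-pair partners (both `;`-separated lists).
#'
#' @param df data.frame with columns `metabolite_id`, `name`, `chem_class`
#'   and optionally `fingerprint`, `compound_id`, `pathways`, `rpairs`.
#' @return validated data.frame of class `metabolite_annotation`.
#' @export
metabolite_annotation <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("metabolite_id", "name", "chem_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metabolite annotation lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$metabolite_id <- as.character(df$metabolite_id)
  if (anyDuplicated(df$metabolite_id))
    stop("duplicate metabolite id: ",
         paste(unique(df$metabolite_id[duplicated(df$metabolite_id)]),
               collapse = ", "))
  bad <- setdiff(unique(df$chem_class), CHEM_CLASSES)
  if (length(bad)) stop("unknown chem_class token: ", paste(bad, collapse = ", "))
  for (v in c("fingerprint", "compound_id", "pathways", "rpairs"))
    if (is.null(df[[v]])) df[[v]] <- NA_character_ else df[[v]] <- as.character(df[[v]])
  fp <- df$fingerprint[!is.na(df$fingerprint) & df$fingerprint != ""]
  if (length(fp)) {
    if (length(unique(nchar(fp))) > 1)
      stop("all fingerprints must share one length")
    if (any(grepl("[^01]", fp)))
      stop("fingerprints must be strings over {0,1}")
  }
  class(df) <- c("metabolite_annotation", "data.frame")
  df
}

#' Binary fingerprint matrix from a metabolite annotation
#'
#' @param metabolites a `metabolite_annotation`.
#' @return integer matrix (metabolites x bits); rows of metabolites without a
#'   fingerprint are dropped.
#' @export
fingerprint_matrix <- function(metabolites) {
  ok <- !is.na(metabolites$fingerprint) & metabolites$fingerprint != ""
  fp <- metabolites$fingerprint[ok]
  if (!length(fp)) return(matrix(integer(0), 0, 0))
  m <- do.call(rbind, lapply(strsplit(fp, ""), as.integer))
  rownames(m) <- metabolites$metabolite_id[ok]
  m
}

#' Pathway membership sets
#'
#' @param metabolites a `metabolite_annotation`.
#' @return named list: pathway name -> character vector of metabolite ids.
#' @export
pathway_sets <- function(metabolites) {
  has <- !is.na(metabolites$pathways) & metabolites$pathways != ""
  if (!any(has)) return(list())
  pairs <- do.call(rbind, lapply(which(has), function(i) {
    data.frame(pathway = strsplit(metabolites$pathways[i], ";", fixed = TRUE)[[1]],
               metabolite_id = metabolites$metabolite_id[i],
               stringsAsFactors = FALSE)
  }))
  split(pairs$metabolite_id, pairs$pathway)
}

#' Reaction-pair (substrate-product) edge table
#'
#' Expands the `;`-separated `rpairs` column into an unordered pair table,
#' deduplicated, keeping only pairs whose two ends are both annotated.
#'
#' @param metabolites a `metabolite_annotation`.
#' @return data.frame with columns `a`, `b` (a < b lexicographically).
#' @export
rpair_table <- function(metabolites) {
  has <- !is.na(metabolites$rpairs) & metabolites$rpairs != ""
  if (!any(has)) return(data.frame(a = character(0), b = character(0)))
  edges <- do.call(rbind, lapply(which(has), function(i) {
    cbind(metabolites$metabolite_id[i],
          strsplit(metabolites$rpairs[i], ";", fixed = TRUE)[[1]])
  }))
  keep <- edges[, 2] %in% metabolites$metabolite_id & edges[, 1] != edges[, 2]
  edges <- edges[keep, , drop = FALSE]
  if (!nrow(edges)) return(data.frame(a = character(0), b = character(0)))
  ab <- t(apply(edges, 1, sort))
  out <- unique(data.frame(a = ab[, 1], b = ab[, 2], stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Validate a dataset triple and align its tables
#'
#' Checks each table's invariants and their cross-references (every matrix
#' row annotated, every annotated sample present, every metabolite
#' annotated) and returns the triple with annotations re-ordered to match
#' the matrix.
#'
#' @param data list with elements `matrix`, `samples`, `metabolites`.
#' @return the validated triple.
#' @export
validate_dataset <- function(data) {
  stopifnot(is.list(data))
  m <- data$matrix; s <- data$samples; a <- data$metabolites
  if (!inherits(m, "metab_matrix")) m <- metabolite_matrix(m)
  if (!inherits(s, "sample_annotation")) s <- sample_annotation(s)
  if (!inherits(a, "metabolite_annotation")) a <- metabolite_annotation(a)
  miss <- setdiff(rownames(m), s$sample_id)
  if (length(miss))
    stop("sample(s) in matrix but not in annotation: ", paste(miss, collapse = ", "))
  extra <- setdiff(s$sample_id, rownames(m))
  if (length(extra))
    stop("sample(s) annotated but absent from matrix: ", paste(extra, collapse = ", "))
  miss <- setdiff(colnames(m), a$metabolite_id)
  if (length(miss))
    stop("metabolite(s) in matrix but not annotated: ", paste(miss, collapse = ", "))
  s <- s[match(rownames(m), s$sample_id), , drop = FALSE]
  rownames(s) <- NULL
  a <- a[match(colnames(m), a$metabolite_id), , drop = FALSE]
  rownames(a) <- NULL
  class(s) <- c("sample_annotation", "data.frame")
  class(a) <- c("metabolite_annotation", "data.frame")
  list(matrix = m, samples = s, metabolites = a)
}

delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else if (ext %in% c("tsv", "txt")) "\t"
  else stop("unrecognised table extension: .", ext, " (use .csv or .tsv)")
}

read_table_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = delim_for(path), header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    quote = "\"", fileEncoding = "UTF-8",
                    stringsAsFactors = FALSE)
}

num_or_na <- function(x) {
  x[x == ""] <- NA_character_
  as.numeric(x)
}

#' Read a dataset triple from delimited files
#'
#' Reads the abundance matrix, sample annotation and metabolite annotation
#' from CSV/TSV files (delimiter auto-detected from the extension; header row
#' and an ID first column required), validates each table and their
#' cross-references, and preserves empty cells as missing values.
#'
#' @param matrix_path,samples_path,metabolites_path file paths.
#' @return list with elements `matrix` (`metab_matrix`), `samples`
#'   (`sample_annotation`), `metabolites` (`metabolite_annotation`).
#' @export
read_dataset <- function(matrix_path, samples_path, metabolites_path) {
  raw <- read_table_file(matrix_path)
  if (ncol(raw) < 2) stop("abundance table needs an id column plus data")
  vals <- as.matrix(raw[, -1, drop = FALSE])
  vals <- apply(vals, 2, num_or_na)
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(raw))
  colnames(vals) <- names(raw)[-1]
  rownames(vals) <- raw[[1]]
  m <- metabolite_matrix(vals)

  sdf <- read_table_file(samples_path)
  names(sdf)[1] <- "sample_id"
  for (v in intersect(c(CLINICAL_VARS, "pre_treatment"), names(sdf)))
    sdf[[v]] <- num_or_na(sdf[[v]])
  s <- sample_annotation(sdf)

  adf <- read_table_file(metabolites_path)
  names(adf)[1] <- "metabolite_id"
  adf[adf == ""] <- NA
  a <- metabolite_annotation(adf)

  validate_dataset(list(matrix = m, samples = s, metabolites = a))
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) if (is.na(v)) "" else sprintf("%.17g", v), "")
  out
}

write_one_table <- function(df, path) {
  sep <- delim_for(path)
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- fmt_num(df[[j]])
    else { df[[j]] <- as.character(df[[j]]); df[[j]][is.na(df[[j]])] <- "" }
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
}

#' Write a dataset triple to delimited files
#'
#' Inverse of [read_dataset()]: writes `matrix.<ext>`, `samples.<ext>` and
#' `metabolites.<ext>` into `dir_path`. Numerics are written with 17
#' significant digits so a round trip restores them bit-identically;
#' missing values become empty cells.
#'
#' @param data dataset triple as returned by [read_dataset()] or
#'   [generate_cohort()].
#' @param dir_path output directory (created if absent).
#' @param format `"csv"` or `"tsv"`.
#' @return invisibly, the three file paths.
#' @export
write_dataset <- function(data, dir_path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (ncol(as.matrix(data$matrix)) == 0) stop("no metabolites to write")
  data <- validate_dataset(data)
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir_path, paste0(c("matrix", "samples", "metabolites"),
                                      ".", format))
  mdf <- data.frame(sample_id = rownames(data$matrix), check.names = FALSE,
                    stringsAsFactors = FALSE)
  vals <- data$matrix
  for (j in seq_len(ncol(vals))) mdf[[colnames(vals)[j]]] <- vals[, j]
  write_one_table(mdf, paths[1])
  write_one_table(data$samples, paths[2])
  write_one_table(data$metabolites, paths[3])
  invisible(paths)
}
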