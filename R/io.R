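# Readers/writers for the tabular formats every stage touches: expression
# and clinical TSV/CSV, GMT gene sets, minimal MAF mutation tables.

sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

#' Read a genes-by-samples expression matrix
#'
#' Expects a delimited text file with gene ids in the first column and one
#' header row of sample ids. The delimiter (tab or comma) is sniffed from
#' the first line unless given.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` (default) sniffs tab vs comma.
#' @param genes_in_rows set `FALSE` for samples-in-rows files; the matrix is
#'   transposed to the canonical genes-by-samples orientation.
#' @return numeric matrix, genes in rows. Duplicate gene ids are collapsed
#'   to the row with maximum mean expression (with a warning); duplicate
#'   sample ids or non-numeric cells are hard errors naming the offender.
#' @export
readExpression <- function(path, sep = NULL, genes_in_rows = TRUE) {
  stopifnot(file.exists(path))
  if (is.null(sep)) sep <- sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]   # before [.data.frame uniquifies them
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  colnames(body) <- sample_ids
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA")
      if (length(bad))
        stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                     ids[bad[1L]], colnames(body)[j], v[bad[1L]]))
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (!genes_in_rows) m <- t(m)
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    warning(sprintf("%d duplicated gene id(s) collapsed by maximum mean expression: %s",
                    length(dup), paste(utils::head(dup, 5L), collapse = ", ")))
    means <- rowMeans(m, na.rm = TRUE)
    keep <- unlist(lapply(split(seq_len(nrow(m)), rownames(m)),
                          function(ix) ix[which.max(means[ix])]))
    m <- m[sort(keep), , drop = FALSE]
  }
  m
}

#' Write an expression matrix as TSV
#' @param m genes-by-samples matrix.
#' @param path output path.
#' @param id_col header for the gene-id column.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(m, path, id_col = "gene_id") {
  df <- data.frame(m[, , drop = FALSE], check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(m)), id_col), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a clinical survival table
#'
#' Requires columns `sample_id`, `os_time` (or `os_time_months`) and
#' `os_event`; optional `rfs_time`/`rfs_time_months`, `rfs_event` and any
#' covariate columns are kept. Times are converted to months according to
#' `time_unit`. Rows with missing survival fields or nonpositive times are
#' dropped with a message; an `os_event` outside {0,1} is an error.
#'
#' @param path file path (delimiter sniffed).
#' @param time_unit unit of the time columns in the file: `"months"`,
#'   `"days"` or `"years"`.
#' @return data.frame with canonical columns `sample_id`, `os_time`,
#'   `os_event` (+ optional `rfs_time`, `rfs_event`, covariates), times in
#'   months.
#' @export
readClinical <- function(path, time_unit = c("months", "days", "years")) {
  stopifnot(file.exists(path))
  time_unit <- match.arg(time_unit)
  fac <- switch(time_unit, months = 1, days = 1 / 30.44, years = 12)
  df <- utils::read.table(path, header = TRUE, sep = sniffSep(path),
                          quote = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  aliases <- c(os_time_months = "os_time", rfs_time_months = "rfs_time",
               os_event_status = "os_event")
  for (alias in names(aliases)) {
    canon <- aliases[[alias]]
    if (alias %in% colnames(df) && !canon %in% colnames(df))
      colnames(df)[colnames(df) == alias] <- canon
  }
  for (col in c("sample_id", "os_time", "os_event"))
    if (!col %in% colnames(df))
      stop(sprintf("clinical table lacks required column '%s'", col))
  if (!all(stats::na.omit(df$os_event) %in% c(0, 1)))
    stop("os_event values outside {0,1}")
  bad <- is.na(df$os_time) | is.na(df$os_event) | df$os_time <= 0
  if (any(bad)) {
    message(sprintf("readClinical: dropped %d row(s) with missing or nonpositive survival fields",
                    sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  df$os_time <- df$os_time * fac
  if ("rfs_time" %in% colnames(df)) df$rfs_time <- df$rfs_time * fac
  rownames(df) <- NULL
  df
}

#' Write a clinical table as TSV
#' @param clinical data.frame as returned by [readClinical()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClinical <- function(clinical, path) {
  df <- clinical
  colnames(df)[colnames(df) == "os_time"] <- "os_time_months"
  colnames(df)[colnames(df) == "rfs_time"] <- "rfs_time_months"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. File order is preserved; duplicate genes within a set are
#' dropped with a warning; a line with fewer than three fields is an error
#' naming the line number. An empty file yields an empty collection.
#'
#' @param path file path.
#' @return [readGMT()] returns a [GeneSetList-class]; [writeGMT()] returns
#'   `path` invisibly.
#' @export
readGMT <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(GeneSetList(stats::setNames(list(), character())))
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': duplicate genes removed", f[1L]))
      genes <- unique(genes)
    }
    sets[[f[1L]]] <- genes
    desc[f[1L]] <- f[2L]
  }
  GeneSetList(sets, desc)
}

#' @rdname readGMT
#' @param gs a [GeneSetList-class].
#' @export
writeGMT <- function(gs, path) {
  stopifnot(is(gs, "GeneSetList"))
  lines <- vapply(names(gs), function(nm) {
    paste(c(nm, gs@descriptions[[nm]], gs[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a minimal MAF mutation table
#'
#' Requires the columns `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification`; other columns are ignored. No classification
#' filtering happens at read time — the nonsynonymous whitelist is applied
#' only when computing TMB.
#'
#' @param path file path.
#' @return [readMAF()] returns a data.frame with the three canonical
#'   columns; [writeMAF()] returns `path` invisibly.
#' @export
readMAF <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("MAF lacks required column(s): ", paste(miss, collapse = ", "))
  df[need]
}

#' @rdname readMAF
#' @param maf data.frame with the three canonical MAF columns.
#' @export
writeMAF <- function(maf, path) {
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  stopifnot(all(need %in% colnames(maf)))
  utils::write.table(maf[need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from an expression file plus a clinical file
#'
#' Convenience wrapper composing [readExpression()], [readClinical()] and
#' the [Cohort()] constructor (sample intersection, sorted order).
#'
#' @param expression_path,clinical_path file paths.
#' @param name cohort identifier.
#' @param ... passed to [readClinical()].
#' @return a [Cohort-class].
#' @export
readCohort <- function(expression_path, clinical_path, name, ...) {
  Cohort(readExpression(expression_path), readClinical(clinical_path, ...),
         name = name)
}

#' Write a cohort as an expression TSV and a clinical TSV
#' @param cohort a [Cohort-class].
#' @param expression_path,clinical_path output paths.
#' @return invisible NULL.
#' @export
writeCohort <- function(cohort, expression_path, clinical_path) {
  writeExpression(exprMatrix(cohort), expression_path)
  writeClinical(clinicalData(cohort), clinical_path)
  invisible(NULL)
}
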