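#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Cohort: an expression matrix joined to clinical survival records
#'
#' A `Cohort` couples a genes-by-samples expression matrix with per-sample
#' survival annotation (overall survival time in months, event indicator,
#' optionally recurrence-free survival and covariates). It extends
#' [SummarizedExperiment::SummarizedExperiment] so the usual accessors
#' (`assay`, `colData`, `dim`, subsetting) all apply; the expression values
#' live in the `"exprs"` assay and the clinical fields in `colData`.
#'
#' Only samples present in both the expression matrix and the clinical table
#' are retained (the intersection, in sorted order); construction fails if
#' the intersection is empty.
#'
#' @slot name single string identifying the cohort (study accession or
#'   simulation label).
#'
#' @seealso [Cohort()] for the validating constructor, [exprMatrix()],
#'   [clinicalData()], [cohortName()].
#' @export
setClass("Cohort",
  contains = "SummarizedExperiment",
  representation(name = "character")
)

setValidity("Cohort", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msgs <- c(msgs, "'name' must be a single non-empty string")
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'exprs' is missing")
  cd <- colData(object)
  for (col in c("os_time", "os_event")) {
    if (!col %in% colnames(cd)) msgs <- c(msgs, sprintf("colData lacks '%s'", col))
  }
  if (all(c("os_time", "os_event") %in% colnames(cd)) && ncol(object) > 0) {
    if (any(!is.finite(cd$os_time)) || any(cd$os_time <= 0))
      msgs <- c(msgs, "os_time must be finite and positive")
    if (!all(cd$os_event %in% c(0, 1)))
      msgs <- c(msgs, "os_event must be 0/1")
  }
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "duplicate gene ids")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Cohort from expression and clinical tables
#'
#' @param expression numeric matrix, genes in rows, samples in columns, with
#'   row and column names.
#' @param clinical data.frame with a `sample_id` column plus `os_time`
#'   (months, positive) and `os_event` (0/1); optional `rfs_time`,
#'   `rfs_event` and arbitrary covariate columns are carried along.
#' @param name cohort identifier.
#'
#' @details Samples are restricted to the intersection of expression column
#'   names and clinical `sample_id`s, in sorted order, so every downstream
#'   stage sees one canonical alignment. A message reports how many samples
#'   were dropped from either side.
#'
#' @return A [Cohort-class] object.
#' @examples
#' expr <- matrix(rnorm(6), 2, 3,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' clin <- data.frame(sample_id = c("s1", "s2", "s3"),
#'   os_time = c(10, 20, 5), os_event = c(1, 0, 1))
#' Cohort(expr, clin, name = "toy")
#' @export
Cohort <- function(expression, clinical, name = "cohort") {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            !is.null(colnames(expression)))
  if (!is.data.frame(clinical) || !"sample_id" %in% colnames(clinical))
    stop("'clinical' must be a data.frame with a 'sample_id' column")
  if (anyDuplicated(clinical$sample_id))
    stop("duplicate sample_id in clinical table")
  if (anyDuplicated(colnames(expression)))
    stop("duplicate sample ids in expression matrix")
  common <- sort(intersect(colnames(expression), clinical$sample_id))
  if (length(common) == 0L)
    stop("expression and clinical tables share no sample ids")
  dropped <- (ncol(expression) - length(common)) +
    (nrow(clinical) - length(common))
  if (dropped > 0)
    message(sprintf("Cohort '%s': %d unmatched sample record(s) dropped; %d samples retained",
                    name, dropped, length(common)))
  clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  cd <- DataFrame(clinical[setdiff(colnames(clinical), "sample_id")],
                  row.names = common)
  se <- SummarizedExperiment(
    assays = list(exprs = expression[, common, drop = FALSE]),
    colData = cd
  )
  new("Cohort", se, name = name)
}

#' @describeIn Cohort one-line summary printed at the console.
#' @param object a `Cohort`.
#' @export
setMethod("show", "Cohort", function(object) {
  cd <- colData(object)
  ev <- if ("os_event" %in% colnames(cd)) sum(cd$os_event) else NA
  cat(sprintf("Cohort '%s': %d genes x %d samples, %s OS events\n",
              object@name, nrow(object), ncol(object), ev))
})

#' Accessors for Cohort objects
#'
#' `exprMatrix` returns the genes-by-samples expression matrix,
#' `clinicalData` the clinical annotation as a data.frame (with `sample_id`
#' restored as a column), and `cohortName` the cohort identifier.
#'
#' @param x a [Cohort-class].
#' @return matrix, data.frame or character scalar respectively.
#' @export
exprMatrix <- function(x) {
  stopifnot(is(x, "Cohort"))
  assay(x, "exprs")
}

#' @rdname exprMatrix
#' @export
clinicalData <- function(x) {
  stopifnot(is(x, "Cohort"))
  cd <- as.data.frame(colData(x))
  cbind(sample_id = rownames(cd), cd, row.names = NULL,
        stringsAsFactors = FALSE)
}

#' @rdname exprMatrix
#' @export
cohortName <- function(x) {
  stopifnot(is(x, "Cohort"))
  x@name
}

#' GeneSetList: a named collection of gene sets
#'
#' Holds named gene sets (character vectors of gene ids, unique within each
#' set, none empty) plus one description string per set — the in-memory
#' counterpart of a GMT file. Used for the immune-cell signature panels and
#' the immune-score signature.
#'
#' @slot sets named list of character vectors.
#' @slot descriptions named character vector, parallel to `sets`.
#' @seealso [GeneSetList()], [readGMT()], [writeGMT()].
#' @export
setClass("GeneSetList",
  representation(sets = "list", descriptions = "character")
)

setValidity("GeneSetList", function(object) {
  msgs <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msgs <- c(msgs, "sets must have unique names")
  if (length(object@descriptions) != length(object@sets))
    msgs <- c(msgs, "one description per set required")
  for (nm in names(object@sets)) {
    g <- object@sets[[nm]]
    if (!is.character(g) || length(g) == 0L)
      msgs <- c(msgs, sprintf("set '%s' is empty or not character", nm))
    else if (anyDuplicated(g))
      msgs <- c(msgs, sprintf("set '%s' has duplicate genes", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSetList
#'
#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled `""` if omitted).
#' @return A [GeneSetList-class].
#' @examples
#' GeneSetList(list(Tcell = c("CD3D", "CD3E"), Bcell = c("CD19", "MS4A1")))
#' @export
GeneSetList <- function(sets, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  new("GeneSetList", sets = sets, descriptions = descriptions)
}

#' @describeIn GeneSetList number of sets.
#' @param x a `GeneSetList`.
#' @export
setMethod("length", "GeneSetList", function(x) length(x@sets))

#' @describeIn GeneSetList set names.
#' @export
setMethod("names", "GeneSetList", function(x) names(x@sets))

#' @describeIn GeneSetList extract one set's gene ids.
#' @param i set name or index.
#' @export
setMethod("[[", "GeneSetList", function(x, i) x@sets[[i]])

#' @describeIn GeneSetList console summary.
#' @param object a `GeneSetList`.
#' @export
setMethod("show", "GeneSetList", function(object) {
  sizes <- lengths(object@sets)
  cat(sprintf("GeneSetList with %d set(s); sizes %s\n", length(object@sets),
              if (length(sizes)) paste0("[", min(sizes), ", ", max(sizes), "]")
              else "[]"))
})

#' @describeIn GeneSetList convert to a plain named list.
#' @export
setMethod("as.list", "GeneSetList", function(x) x@sets)
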