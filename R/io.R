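# Matrix and model I/O: cohorts as CSV/TSV (samples x features, header row
# of feature names, outcome in a sibling file), models as human-auditable
# JSON -- matching the privacy stance that only model parameters, never raw
# data, leave a server.

MODEL_FORMAT_VERSION <- "1.0"

sep_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a cohort from a matrix file and an outcome file
#'
#' @param matrix_path CSV or TSV file (by extension), first row feature
#'   names, one sample per row, numeric cells only.
#' @param outcome_path File with one outcome value per sample (no header).
#' @param task_id Cohort identifier (default: the matrix file stem).
#' @param outcome `"continuous"` or `"binary"`.
#' @return A validated [task_dataset()].
#' @export
read_cohort <- function(matrix_path, outcome_path,
                        task_id = sub("\\.[^.]*$", "",
                                      basename(matrix_path)),
                        outcome = c("continuous", "binary")) {
  outcome <- match.arg(outcome)
  df <- utils::read.table(matrix_path, header = TRUE,
                          sep = sep_for(matrix_path),
                          check.names = FALSE)
  non_num <- !vapply(df, is.numeric, logical(1))
  if (any(non_num))
    stop("non-numeric cells in column(s): ",
         paste(names(df)[non_num], collapse = ", "), " of ", matrix_path)
  X <- as.matrix(df)
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1L, ]
    stop("missing value at row ", bad[1L], ", column ", bad[2L],
         " of ", matrix_path)
  }
  y <- scan(outcome_path, what = numeric(), quiet = TRUE)
  if (length(y) != nrow(X))
    stop("outcome length (", length(y), ") != sample count (", nrow(X),
         ")")
  task_dataset(X, y, feature_names = colnames(X), task_id = task_id,
               outcome = outcome)
}

#' Write a cohort to a matrix file and an outcome file
#'
#' @param dataset A [task_dataset()].
#' @param matrix_path,outcome_path Output paths (CSV or TSV by extension).
#' @return The matrix path, invisibly.
#' @export
write_cohort <- function(dataset, matrix_path, outcome_path) {
  utils::write.table(dataset$X, matrix_path, sep = sep_for(matrix_path),
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  writeLines(format(dataset$y, digits = 17, trim = TRUE, scientific = FALSE),
             outcome_path)
  invisible(matrix_path)
}

#' Serialize a fitted model to JSON
#'
#' Coefficient models are written with their full coefficient matrix and
#' intercepts; iNMF models are written with the shared metagene matrix `H`
#' and the scalar objective only, honoring the shared-only policy under
#' which the cohort-specific factors never reached the client in the first
#' place.
#'
#' @param model A [coef_model()], `solve_result`, `cv_result` or
#'   `inmf_model`.
#' @param path Output JSON path.
#' @param algorithm,seed Optional metadata recorded in the file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, algorithm = NULL, seed = NULL) {
  meta <- list(version = MODEL_FORMAT_VERSION, algorithm = algorithm,
               seed = seed)
  if (inherits(model, "cv_result")) {
    meta$lambda <- model$lambda_best
    model <- model$model
  }
  if (inherits(model, "solve_result")) {
    meta$lambda <- model$lambda
    meta$comm <- model$comm[c("rounds", "total_accesses")]
    model <- model$model
  }
  if (inherits(model, "coef_model")) {
    obj <- c(meta, list(
      type = "coef_model", loss = model$loss,
      feature_names = model$feature_names, task_ids = model$task_ids,
      W = unname(model$W), c = unname(model$c)))
  } else if (inherits(model, "inmf_model")) {
    obj <- c(meta, list(
      type = "inmf_model", rank = model$rank,
      lambda_het = model$lambda_het, objective = model$objective,
      gene_names = model$gene_names, H = unname(model$H),
      comm = model$comm[c("rounds", "total_accesses")]))
  } else stop("cannot serialize objects of class ",
              paste(class(model), collapse = "/"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model serialized by [write_model()]
#'
#' @param path JSON path.
#' @return A [coef_model()] or a reduced `inmf_model` (H and objective),
#'   with the file's metadata in attribute `"meta"`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$version) || !identical(obj$version,
                                         MODEL_FORMAT_VERSION))
    stop("unsupported model format version: ",
         if (is.null(obj$version)) "<missing>" else obj$version)
  if (identical(obj$type, "coef_model")) {
    W <- matrix(unlist(obj$W), nrow = length(obj$feature_names),
                ncol = length(obj$task_ids))
    m <- coef_model(W, obj$c, obj$feature_names, obj$task_ids, obj$loss)
  } else if (identical(obj$type, "inmf_model")) {
    H <- matrix(unlist(obj$H), ncol = length(obj$gene_names))
    m <- structure(list(H = H, objective = obj$objective,
                        rank = obj$rank, lambda_het = obj$lambda_het,
                        gene_names = obj$gene_names,
                        start_objectives = numeric(0),
                        comm = obj$comm),
                   class = "inmf_model")
  } else stop("unknown model type in ", path)
  attr(m, "meta") <- obj[c("algorithm", "seed", "lambda", "comm")]
  m
}
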