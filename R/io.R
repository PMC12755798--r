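#' Read and write trait tables and result objects
#'
#' Plain-text serialization: trait tables as TSV (header row of function
#' labels, one row per species), structures and equilibrium states as JSON,
#' function time series as TSV. Every writer has a reader for which
#' write-then-read is the identity (up to double-precision printing, which
#' the JSON writers avoid by storing full precision).
#'
#' @param structure a [community_structure()].
#' @param path file path.
#' @name structglv-io
NULL

#' @rdname structglv-io
#' @export
write_traits_tsv <- function(structure, path) {
  stopifnot(inherits(structure, "community_structure"))
  lab <- structure$labels
  if (is.null(lab)) lab <- paste0("f", seq_len(structure$n_functions))
  tab <- data.frame(structure$impact, structure$sensitivity,
                    check.names = FALSE)
  names(tab) <- c(paste0("impact.", lab), paste0("sensitivity.", lab))
  if (!is.null(structure$group_ids)) tab$group <- structure$group_ids
  utils::write.table(format(tab, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname structglv-io
#' @export
read_traits_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  icol <- grep("^impact\\.", names(tab))
  scol <- grep("^sensitivity\\.", names(tab))
  if (!length(icol) || length(icol) != length(scol))
    stop("malformed trait table: need matching impact.* and sensitivity.* columns")
  gid <- if ("group" %in% names(tab)) tab$group else NULL
  community_structure(as.matrix(tab[icol]), as.matrix(tab[scol]),
                      labels = sub("^impact\\.", "", names(tab)[icol]),
                      group_ids = gid, check_low_rank = FALSE)
}

#' @rdname structglv-io
#' @export
write_structure_json <- function(structure, path) {
  stopifnot(inherits(structure, "community_structure"))
  jsonlite::write_json(
    list(impact = structure$impact, sensitivity = structure$sensitivity,
         labels = structure$labels, group_ids = structure$group_ids),
    path, digits = NA, auto_unbox = FALSE, null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname structglv-io
#' @export
read_structure_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("impact", "sensitivity"))
    if (is.null(obj[[field]]))
      stop("malformed structure file: missing field '", field, "'")
  community_structure(obj$impact, obj$sensitivity,
                      labels = obj$labels, group_ids = obj$group_ids,
                      check_low_rank = FALSE)
}

#' Serialize an equilibrium state to JSON
#'
#' @param state a `glv_equilibrium`.
#' @param path file path.
#' @export
write_equilibrium_json <- function(state, path) {
  stopifnot(inherits(state, "glv_equilibrium"))
  jsonlite::write_json(
    list(sigma = state$sigma, f_star = state$f_star, gamma = state$gamma,
         C_star = state$C_star, phi_star = state$phi_star,
         modal = state$modal, survival = state$survival,
         residual = state$residual, converged = state$converged),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_equilibrium_json
#' @export
read_equilibrium_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("sigma", "f_star", "gamma", "modal"))
    if (is.null(obj[[field]]))
      stop("malformed equilibrium file: missing field '", field, "'")
  obj
}

#' Export a collective-function time series as TSV
#'
#' @param traj a `glv_sim`.
#' @param path file path.
#' @export
write_functions_tsv <- function(traj, path) {
  stopifnot(inherits(traj, "glv_sim"))
  lab <- traj$system$structure$labels
  if (is.null(lab)) lab <- paste0("f", seq_len(nrow(traj$functions)))
  tab <- data.frame(time = traj$times, t(traj$functions))
  names(tab) <- c("time", lab)
  utils::write.table(format(tab, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_functions_tsv
#' @export
read_functions_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  if (names(tab)[1] != "time") stop("malformed time series: no 'time' column")
  list(times = tab$time, functions = t(as.matrix(tab[-1])))
}

#' Serialize a stability report to JSON
#'
#' Eigenvalues are stored as (re, im) pairs.
#'
#' @param report a `stability_report`.
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "stability_report"))
  jsonlite::write_json(
    list(sigma = report$sigma, bulk_index = report$bulk_index,
         leading_real_part = report$leading_real_part,
         classification = report$classification,
         outliers = cbind(re = Re(report$outliers), im = Im(report$outliers))),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$classification))
    stop("malformed report file: missing field 'classification'")
  if (length(obj$outliers))
    obj$outliers <- complex(real = obj$outliers[, 1],
                            imaginary = obj$outliers[, 2])
  obj
}
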