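#' Read and write count-pair samples
#'
#' The standard on-disk format is tab-separated text with a header: columns
#' `x` and `y` (one row per trial) and optionally `stimulus`.
#'
#' @param path File path.
#' @return A [count_pairs()] sample.
#' @export
read_count_pairs <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(d)))
    stop("parse error: expected columns `x` and `y` in ", path)
  count_pairs(d$x, d$y, stimulus = d$stimulus)
}

#' @rdname read_count_pairs
#' @param s A [count_pairs()] sample.
#' @export
write_count_pairs <- function(s, path) {
  utils::write.table(as.data.frame(s), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read spike trains from delimited text
#'
#' One line per trial: space-separated spike times in seconds. The duration
#' is either supplied or taken as the latest spike time across trials.
#'
#' @param path File path.
#' @param duration_s Optional common duration in seconds.
#' @return A list of [spike_train()] objects.
#' @export
read_spike_trains <- function(path, duration_s = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  trains <- lapply(lines, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (is.null(duration_s))
    duration_s <- max(vapply(trains, function(t)
      if (length(t)) max(t) else 0, numeric(1)))
  lapply(trains, spike_train, duration = duration_s)
}

#' Serialize a fitted maximum entropy model to JSON
#'
#' Dumps rates, correlation, support bounds, solved multipliers and tolerance
#' metadata; [maxent_model_from_json()] reconstructs the model (refitting the
#' table from the stored parameters).
#'
#' @param model A [fit_maxent()] result.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @export
maxent_model_to_json <- function(model, path = NULL) {
  x <- list(rate_x = model$rate_x, rate_y = model$rate_y, rho = model$rho,
            support = list(max_x = model$support$max_x,
                           max_y = model$support$max_y),
            theta = model$theta,
            row_factors = model$row_factors,
            col_factors = model$col_factors,
            constraint_tol = model$constraint_tol,
            residual = model$residual, clipped = model$clipped)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname maxent_model_to_json
#' @param json JSON string or file path produced by [maxent_model_to_json()].
#' @export
maxent_model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  fit_maxent(x$rate_x, x$rate_y, x$rho,
             support = support_from_dims(x$support$max_x + 1L,
                                         x$support$max_y + 1L),
             constraint_tol = x$constraint_tol)
}

#' Serialize a test result to JSON
#'
#' All fields of the result plus the divergence name and annealing
#' configuration, for provenance.
#'
#' @param result A [run_test()] result.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @export
test_result_to_json <- function(result, path = NULL) {
  x <- unclass(result)
  x$anneal <- unclass(x$anneal)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
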