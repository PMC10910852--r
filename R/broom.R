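# tidy()/glance() methods ----------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.spacer_null <- function(x, ...) {
  tibble(value = x$values)
}

#' @exportS3Method generics::glance
glance.spacer_null <- function(x, ...) {
  tibble(
    n_replicates = x$n_replicates,
    index = x$index,
    n_values = length(x$values),
    threshold_95 = threshold_from_null(x, 95)
  )
}

#' @exportS3Method generics::tidy
tidy.module_partition <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.module_partition <- function(x, ...) {
  sizes <- table(x$module)
  tibble(
    n_modules = length(sizes),
    n_singletons = sum(sizes == 1L),
    largest = max(sizes),
    method = attr(x, "method")
  )
}

#' @exportS3Method generics::tidy
tidy.mcl_partition <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.mcl_partition <- function(x, ...) {
  tibble(
    n_clusters = max(x$cluster),
    largest = max(table(x$cluster)),
    iterations = attr(x, "iterations"),
    converged = attr(x, "converged"),
    inflation = attr(x, "inflation")
  )
}

#' @exportS3Method generics::tidy
tidy.self_target_scan <- function(x, ...) {
  x$events
}

#' @exportS3Method generics::glance
glance.self_target_scan <- function(x, ...) {
  tibble(
    n_events = nrow(x$events),
    n_spacers = dplyr::n_distinct(x$events$spacer_id),
    n_plasmid_only = nrow(x$plasmid_only)
  )
}

#' @exportS3Method generics::glance
glance.spacer_run <- function(x, ...) {
  as_tibble(x$summary)
}
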