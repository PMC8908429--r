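# Text-format import/export ---------------------------------------------

#' Write / read a per-trial kinematic table as CSV
#'
#' Fixed column order: subject, trial, distance_cm, direction, rt_s,
#' mt_s, tmt_s, pv_cm_s, pv_t_s, extent_cm, kept (extra columns are
#' appended after these).
#'
#' @param table Per-trial table.
#' @param path File path.
#' @export
write_trials_csv <- function(table, path) {
  first <- c("subject", "trial", "distance_cm", "direction", "rt_s",
             "mt_s", "tmt_s", "pv_cm_s", "pv_t_s", "extent_cm", "kept")
  cols <- c(intersect(first, names(table)),
            setdiff(names(table), first))
  utils::write.csv(table[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) utils::read.csv(path)

#' Write / read a channel layout as JSON
#'
#' @param layout A `reach_layout`.
#' @param path File path.
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(
    list(names = layout$names,
         pos2d = unname(apply(layout$pos2d, 1, as.numeric,
                              simplify = FALSE)),
         neighbors = lapply(layout$neighbors, as.integer),
         region = layout$region),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- x$pos2d
  if (is.list(p)) p <- do.call(rbind, lapply(p, unlist))
  colnames(p) <- c("x", "y")
  structure(list(names = x$names,
                 pos2d = p,
                 neighbors = lapply(x$neighbors, as.integer),
                 region = x$region),
            class = "reach_layout")
}

#' Read / write a generator configuration as YAML
#'
#' The YAML mirrors the arguments of [synth_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return A validated `synth_config`.
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(synth_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "))
  do.call(synth_config, x)
}

#' @rdname read_config_yaml
#' @param cfg A `synth_config`.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a run report (or any result list) as JSON
#'
#' @param report Nested list.
#' @param path File path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Serialize a cluster permutation result to JSON
#'
#' Cluster members are written as channel-name + bin-index lists; the
#' seed and permutation count are always recorded.
#'
#' @param result A `cluster_result`.
#' @param path File path.
#' @param ch_names Channel names for the member lists.
#' @export
write_cluster_json <- function(result, path, ch_names = NULL) {
  clusters <- lapply(result$clusters, function(cl) {
    ch <- cl$members[, "channel"]
    list(channels = if (is.null(ch_names)) as.integer(ch)
                    else ch_names[ch],
         bins = as.integer(cl$members[, "bin"]),
         mass = cl$mass, sign = cl$sign, p = cl$p, ci = cl$ci)
  })
  jsonlite::write_json(
    list(kind = result$kind, threshold = result$threshold,
         min_neighbors = result$min_neighbors, n_perm = result$n_perm,
         seed = result$seed, clusters = clusters),
    path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Serialize an NBS result to JSON
#'
#' @param result An `nbs_result`.
#' @param path File path.
#' @param ch_names Optional node names.
#' @export
write_nbs_json <- function(result, path, ch_names = NULL) {
  comps <- lapply(result$components, function(cm) {
    a <- cm$pairs[, 1]; b <- cm$pairs[, 2]
    if (!is.null(ch_names)) { a <- ch_names[a]; b <- ch_names[b] }
    list(node_a = a, node_b = b, n_edges = cm$n_edges,
         n_nodes = cm$n_nodes, size = cm$size, p = cm$p,
         significant = cm$significant)
  })
  jsonlite::write_json(
    list(kind = result$kind, threshold = result$threshold,
         mode = result$mode, n_perm = result$n_perm, seed = result$seed,
         components = comps),
    path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
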