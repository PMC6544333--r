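#' Write a causal edge list as TSV
#'
#' Columns `cause`, `effect`, `lag`, `coefficient`, `sign`,
#' `intraspecific`, `strong`, sorted by (effect, cause, lag) for
#' deterministic output; an empty list yields a header-only file.
#'
#' @param edges edge data.frame.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  cols <- c("cause", "effect", "lag", "coefficient", "sign",
            "intraspecific", "strong")
  stopifnot(all(cols %in% colnames(edges)))
  edges <- edges[order(edges$effect, edges$cause, edges$lag), cols,
                 drop = FALSE]
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a causal edge list written by [write_edge_list()]
#'
#' @param path file to read.
#' @return edge data.frame.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  df$lag <- as.integer(df$lag)
  df$sign <- as.integer(df$sign)
  df$intraspecific <- as.logical(df$intraspecific)
  df$strong <- as.logical(df$strong)
  df
}

#' Export an edge set as a GraphML network
#'
#' Directed multigraph with `lag`, `coefficient`, `sign` and `strong`
#' edge attributes, readable by standard network tools.
#'
#' @param edges edge data.frame.
#' @param path destination `.graphml` file.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(edges, path) {
  vs <- sort(unique(c(edges$cause, edges$effect)))
  g <- igraph::graph_from_data_frame(
    edges[, c("cause", "effect", "lag", "coefficient", "sign", "strong")],
    directed = TRUE, vertices = data.frame(name = vs))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Run the full causal-network pipeline over one or more body sites
#'
#' Per site: preprocessing, per-genus lasso VAR fits, edge extraction,
#' strong-edge marking, timescale classification, reshuffling null run
#' with overlap filtering, Pearson network and short/long sign
#' contingencies. Across sites (when more than one): shared-taxa counts
#' and pairwise strong-edge conservation reports. All seeds derive from
#' `config$seed`.
#'
#' @param config a [run_config()].
#' @param tables named list of [genus_table()] objects, one per site.
#' @param out_dir optional directory; when given, per-site edge lists,
#'   strong networks (GraphML), null summaries and a config log are
#'   written there.
#' @return an object of class `gc_archive`: list with one entry per site
#'   (each holding `processed`, `tensor`, `edges`, `strong`, `calls`,
#'   `null`, `filtered_strong`, `pearson`, `contingency`), plus
#'   `conservation` and `shared` across sites, and the echoed `config`.
#' @export
run_pipeline <- function(config, tables, out_dir = NULL) {
  validate_run_config(config)
  if (!length(tables)) stop("need at least one site table")
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t) t$site, "")
  sites <- list()
  for (nm in names(tables)) {
    res <- tryCatch({
      tab <- tables[[nm]]
      processed <- preprocess(tab, config)
      tensor <- fit_all_responses(processed, config)
      edges <- extract_edges(tensor)
      strong <- mark_strong(edges, config$strong_percentile, site = nm)
      calls <- classify_timescales(strong$edges[strong$edges$strong, ,
                                                drop = FALSE],
                                   config$short_range, config$long_range)
      null <- null_run(processed, config, strong)
      filtered <- overlap_filter(
        strong$edges[strong$edges$strong, , drop = FALSE],
        null$null_edges[null$null_edges$strong, , drop = FALSE])
      pearson <- pearson_network(processed, config$alpha)
      conting <- list(
        short = sign_contingency(pearson, calls, "short", site = nm),
        long = sign_contingency(pearson, calls, "long", site = nm))
      list(table = tab, processed = processed, tensor = tensor,
           edges = strong$edges, strong = strong, calls = calls,
           null = null, filtered_strong = filtered, pearson = pearson,
           contingency = conting)
    }, error = function(e)
      stop("pipeline failed at site '", nm, "': ", conditionMessage(e),
           call. = FALSE))
    sites[[nm]] <- res
  }
  conservation <- NULL
  shared <- NULL
  if (length(sites) >= 2) {
    shared <- shared_taxa(lapply(sites, function(s) s$processed$taxa))
    cmb <- combn(names(sites), 2)
    conservation <- apply(cmb, 2, function(p) {
      a <- sites[[p[1]]]; b <- sites[[p[2]]]
      list(site_a = p[1], site_b = p[2],
           quantitative = conserved_edges(
             a$edges, b$edges, a$processed$taxa, b$processed$taxa,
             "quantitative", "strong"),
           qualitative = conserved_edges(
             a$edges, b$edges, a$processed$taxa, b$processed$taxa,
             "qualitative", "strong", calls_a = a$calls, calls_b = b$calls,
             short_range = config$short_range,
             long_range = config$long_range))
    }, simplify = FALSE)
  }
  archive <- structure(list(sites = sites, shared = shared,
                            conservation = conservation, config = config),
                       class = "gc_archive")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(sites)) {
      s <- sites[[nm]]
      write_edge_list(s$edges, file.path(out_dir, paste0(nm, "_edges.tsv")))
      write_edge_list(s$filtered_strong,
                      file.path(out_dir, paste0(nm, "_strong.tsv")))
      if (nrow(s$filtered_strong))
        export_graphml(s$filtered_strong,
                       file.path(out_dir, paste0(nm, "_strong.graphml")))
    }
    cfg <- config
    writeLines(c(paste0(names(unlist(cfg)), "\t", unlist(cfg)),
                 paste0("site\t", names(sites))),
               file.path(out_dir, "run_config.log"))
  }
  archive
}

#' @export
print.gc_archive <- function(x, ...) {
  cat("gc_archive:", length(x$sites), "site(s):",
      paste(names(x$sites), collapse = ", "), "\n")
  for (nm in names(x$sites)) {
    s <- x$sites[[nm]]
    cat("  ", nm, ": ", nrow(s$edges), " edges, ",
        sum(s$edges$strong), " strong (", nrow(s$filtered_strong),
        " after null overlap filter)\n", sep = "")
  }
  invisible(x)
}
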