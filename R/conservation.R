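#' Shared genera across body sites
#'
#' Exact set algebra over the sites' taxa lists: pairwise intersections,
#' the overall union/intersection, and exclusive Venn region counts (how
#' many genera occur in exactly each site combination).
#'
#' @param tables named list of [genus_table()] objects (or plain character
#'   vectors of taxa), length >= 2.
#' @return list with `taxa` (per-site lists), `pairwise` (data.frame
#'   `site_a`, `site_b`, `n_shared`, `n_union`, `jaccard`), `venn` (named
#'   exclusive region counts), `n_union`, `n_core`.
#' @export
shared_taxa <- function(tables) {
  if (length(tables) < 2) stop("need at least 2 sites")
  taxa <- lapply(tables, function(t) if (is.character(t)) t else t$taxa)
  if (is.null(names(taxa)) || any(!nzchar(names(taxa))))
    names(taxa) <- paste0("site", seq_along(taxa))
  sites <- names(taxa)
  pw <- do.call(rbind, apply(combn(sites, 2), 2, function(p) {
    a <- taxa[[p[1]]]; b <- taxa[[p[2]]]
    data.frame(site_a = p[1], site_b = p[2],
               n_shared = length(intersect(a, b)),
               n_union = length(union(a, b)),
               jaccard = length(intersect(a, b)) / length(union(a, b)),
               stringsAsFactors = FALSE)
  }, simplify = FALSE))
  all_taxa <- unique(unlist(taxa))
  member <- sapply(taxa, function(s) all_taxa %in% s)
  region <- apply(member, 1, function(m) paste(sites[m], collapse = "&"))
  venn <- table(region)
  list(taxa = taxa, pairwise = pw, venn = venn,
       n_union = length(all_taxa),
       n_core = length(Reduce(intersect, taxa)))
}

#' Conserved edges between two body sites
#'
#' Quantitative conservation requires identical (cause, effect, lag) and
#' coefficient sign; qualitative conservation requires the same ordered
#' pair with the same sign in the same timescale window (short/long),
#' excluding pairs with conflicting window signs. Comparison is restricted
#' to edges whose cause and effect both occur in BOTH sites' taxa lists.
#'
#' @param edges_a,edges_b edge data.frames of the two sites.
#' @param taxa_a,taxa_b full taxa lists of the two sites.
#' @param mode `"quantitative"` or `"qualitative"`.
#' @param scope `"strong"` (default, strong edges only) or `"all"`.
#' @param calls_a,calls_b [classify_timescales()] results, required for
#'   qualitative mode (built from the in-scope edges).
#' @param short_range,long_range windows used when `calls_*` are absent.
#' @return an object of class `conservation_report`: list with `shared`
#'   (genus vector), `conserved` (data.frame of matching keys),
#'   `fractions` (interspecific and intraspecific conserved / union, `NA`
#'   when the union is empty), and the per-class union sizes.
#' @export
conserved_edges <- function(edges_a, edges_b, taxa_a, taxa_b,
                            mode = c("quantitative", "qualitative"),
                            scope = c("strong", "all"),
                            calls_a = NULL, calls_b = NULL,
                            short_range = c(1L, 5L), long_range = c(15L, 20L)) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  shared <- intersect(taxa_a, taxa_b)
  pick <- function(e) {
    if (scope == "strong") e <- e[e$strong, , drop = FALSE]
    e[e$cause %in% shared & e$effect %in% shared, , drop = FALSE]
  }
  ea <- pick(edges_a)
  eb <- pick(edges_b)
  if (mode == "quantitative") {
    keys <- function(e) data.frame(
      cause = e$cause, effect = e$effect, lag = e$lag, sign = e$sign,
      intraspecific = e$intraspecific, stringsAsFactors = FALSE)
    ka <- unique(keys(ea)); kb <- unique(keys(eb))
  } else {
    wcalls <- function(e, calls) {
      if (is.null(calls)) calls <- classify_timescales(e, short_range,
                                                       long_range)
      calls <- calls[calls$cause %in% shared & calls$effect %in% shared, ,
                     drop = FALSE]
      long <- rbind(
        data.frame(cause = calls$cause, effect = calls$effect,
                   intraspecific = calls$intraspecific,
                   window = "short", sign = calls$short_sign,
                   stringsAsFactors = FALSE),
        data.frame(cause = calls$cause, effect = calls$effect,
                   intraspecific = calls$intraspecific,
                   window = "long", sign = calls$long_sign,
                   stringsAsFactors = FALSE))
      long[long$sign %in% c("positive", "negative"), , drop = FALSE]
    }
    ka <- unique(wcalls(ea, calls_a)); kb <- unique(wcalls(eb, calls_b))
  }
  kstr <- function(k) do.call(paste, c(as.list(k), sep = "\r"))
  conserved <- ka[kstr(ka) %in% kstr(kb), , drop = FALSE]
  rownames(conserved) <- NULL
  frac <- function(intra) {
    ua <- ka[ka$intraspecific == intra, , drop = FALSE]
    ub <- kb[kb$intraspecific == intra, , drop = FALSE]
    nun <- length(unique(c(kstr(ua), kstr(ub))))
    ncon <- sum(conserved$intraspecific == intra)
    list(n_union = nun,
         fraction = if (nun > 0) ncon / nun else NA_real_)
  }
  fi <- frac(FALSE); fs <- frac(TRUE)
  structure(list(mode = mode, scope = scope, shared = shared,
                 conserved = conserved,
                 fractions = c(interspecific = fi$fraction,
                               intraspecific = fs$fraction),
                 n_union = c(interspecific = fi$n_union,
                             intraspecific = fs$n_union)),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat("conservation_report (", x$mode, ", ", x$scope, " edges): ",
      length(x$shared), " shared genera; ", nrow(x$conserved),
      " conserved record(s)\n", sep = "")
  cat("fractions (conserved / union over shared taxa): interspecific ",
      format(x$fractions["interspecific"]), ", intraspecific ",
      format(x$fractions["intraspecific"]), "\n", sep = "")
  invisible(x)
}

#' Conserved fractions from a conservation report
#'
#' Fraction = conserved records / union of the two sites' in-scope records
#' restricted to shared taxa (Jaccard-style), reported separately for
#' interspecific and intraspecific edges; `NA` when a union is empty.
#'
#' @param report a `conservation_report`.
#' @return named numeric vector `interspecific`, `intraspecific`.
#' @export
conservation_fractions <- function(report) {
  stopifnot(inherits(report, "conservation_report"))
  report$fractions
}
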