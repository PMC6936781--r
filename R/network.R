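#' Genus-flavor correlation matrix
#'
#' Correlation between every genus (relative abundance) and every flavor
#' component across samples. Pearson is the default; Spearman by flag.
#' Constant rows or columns have no defined correlation and are returned
#' as `NA`, never silently zero. Optionally both blocks can be
#' log-transformed first with a pseudocount of half the smallest positive
#' value.
#'
#' @param x abundance_table (used as proportions) or matrix.
#' @param y flavor_table or matrix, aligned samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param log_transform apply log10(value + pseudocount) to both blocks.
#' @return genus-by-flavor correlation matrix in `[-1, 1]` (with `NA` for
#'   undefined entries).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      log_transform = FALSE) {
  method <- match.arg(method)
  xv <- block_values(x, as_proportions = TRUE)
  yv <- block_values(y)
  if (nrow(xv) != nrow(yv)) stop("X and Y must have the same samples")
  if (nrow(xv) < 3) stop("correlation needs at least 3 samples")
  if (log_transform) {
    xv <- log_pseudo(xv)
    yv <- log_pseudo(yv)
  }
  suppressWarnings(stats::cor(xv, yv, method = method))
}

log_pseudo <- function(v) {
  pos <- v[v > 0]
  pc <- if (length(pos)) min(pos) / 2 else 1
  log10(v + pc)
}

#' Threshold a correlation matrix into a signed bipartite network
#'
#' Keeps the edges with `|r|` strictly greater than `cutoff` (matching a
#' "> 0.7" reading of the threshold); undefined (`NA`) correlations are
#' excluded.
#'
#' @param r_matrix genus-by-flavor correlation matrix.
#' @param cutoff threshold in (0, 1); conventional values 0.7 and 0.8.
#' @return object of class `correlation_network`: data.frame with columns
#'   `genus`, `flavor`, `r`, `sign`; attributes `threshold`, `genera`,
#'   `flavors` (the full node sets, including unconnected genera).
#' @export
threshold_network <- function(r_matrix, cutoff = 0.7) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  r_matrix <- as.matrix(r_matrix)
  idx <- which(!is.na(r_matrix) & abs(r_matrix) > cutoff, arr.ind = TRUE)
  edges <- data.frame(
    genus = rownames(r_matrix)[idx[, 1]],
    flavor = colnames(r_matrix)[idx[, 2]],
    r = r_matrix[idx],
    sign = ifelse(r_matrix[idx] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$genus, edges$flavor), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, class = c("correlation_network", "data.frame"),
            threshold = cutoff,
            genera = rownames(r_matrix), flavors = colnames(r_matrix))
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation network (|r| > %g): %d edges, %d genera x %d flavors\n",
              attr(x, "threshold"), nrow(x), length(attr(x, "genera")),
              length(attr(x, "flavors"))))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Per-genus partner counts in a thresholded network
#'
#' Counts, for every genus in the correlation matrix (including genera with
#' no edges), its flavor partners in total and split into AA and VF
#' partners, and lists the genera correlated with at least one AA, at least
#' one VF, and with both classes.
#'
#' @param net `correlation_network`.
#' @param ann annotation resolving every flavor id to a kind.
#' @return object of class `partner_summary`: data.frame (`genus`, `total`,
#'   `aa_partners`, `vf_partners`) plus attributes `aa_genera`,
#'   `vf_genera`, `both_genera`.
#' @export
partner_summary <- function(net, ann) {
  stopifnot(inherits(net, "correlation_network"))
  ann <- validate_annotation(ann)
  flavors <- attr(net, "flavors")
  unknown <- setdiff(flavors, ann$component_id)
  if (length(unknown))
    stop("unannotated flavor component(s): ", paste(unknown, collapse = ", "))
  kind <- ann$kind[match(net$flavor, ann$component_id)]
  genera <- attr(net, "genera")
  count_for <- function(sel) {
    tb <- table(factor(net$genus[sel], levels = genera))
    as.integer(tb)
  }
  out <- data.frame(genus = genera,
                    total = count_for(rep(TRUE, nrow(net))),
                    aa_partners = count_for(kind == "AA"),
                    vf_partners = count_for(kind == "VF"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("partner_summary", "data.frame"),
            aa_genera = out$genus[out$aa_partners >= 1],
            vf_genera = out$genus[out$vf_partners >= 1],
            both_genera = out$genus[out$aa_partners >= 1 &
                                      out$vf_partners >= 1])
}

#' Screen for the functional core microbiota
#'
#' Applies the three-criterion screen: a genus belongs to the functional
#' core when it (i) correlates with both AAs and VFs (at least one partner
#' of each class), (ii) has VIP(pred) of at least `vip_cut` (inclusive),
#' and (iii) has at least `partner_cut` flavor partners in total at the
#' network's threshold (inclusive). Edge membership itself is strict
#' (`|r| >` threshold) while the VIP and partner cuts are inclusive,
#' matching the "at least" phrasing of the criteria.
#'
#' @param summary `partner_summary` built at the screening threshold
#'   (conventionally `|r| > 0.7`).
#' @param vip named VIP(pred) vector covering the same genus set (see
#'   [vip_pred()]).
#' @param vip_cut VIP criterion (default 1.00).
#' @param partner_cut partner-count criterion (default 16).
#' @return object of class `core_screen`: data.frame with per-genus
#'   criteria columns and `core` flag; attribute `core_set` holds the core
#'   genus ids.
#' @export
screen_core <- function(summary, vip, vip_cut = 1.00, partner_cut = 16) {
  stopifnot(inherits(summary, "partner_summary"))
  if (is.null(names(vip))) stop("vip must be a named vector")
  missing_v <- setdiff(summary$genus, names(vip))
  if (length(missing_v))
    stop("genus in summary missing from VIP: ",
         paste(missing_v, collapse = ", "))
  v <- vip[summary$genus]
  out <- data.frame(
    genus = summary$genus,
    correlates_with_AA = summary$aa_partners >= 1,
    correlates_with_VF = summary$vf_partners >= 1,
    vip = unname(v),
    n_flavor_partners = summary$total,
    stringsAsFactors = FALSE)
  out$criterion_i <- out$correlates_with_AA & out$correlates_with_VF
  out$criterion_ii <- out$vip >= vip_cut
  out$criterion_iii <- out$n_flavor_partners >= partner_cut
  out$core <- out$criterion_i & out$criterion_ii & out$criterion_iii
  structure(out, class = c("core_screen", "data.frame"),
            core_set = out$genus[out$core],
            vip_cut = vip_cut, partner_cut = partner_cut)
}

#' @export
print.core_screen <- function(x, ...) {
  core <- attr(x, "core_set")
  cat(sprintf("core screen (VIP >= %g, partners >= %d): %d of %d genera are core\n",
              attr(x, "vip_cut"), attr(x, "partner_cut"), length(core),
              nrow(x)))
  if (length(core)) cat("core:", paste(core, collapse = ", "), "\n")
  invisible(x)
}

#' Export a correlation network
#'
#' `edge_tsv` writes the edge list (genus, flavor, r, sign) and round-trips
#' losslessly through [read_network()]. `graphml` writes a bipartite graph
#' with node attributes (`side`; flavor `kind` and `category` when an
#' annotation is given) and edge attributes (`r`, `sign`).
#'
#' @param net `correlation_network`.
#' @param path output file.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @param ann optional annotation for flavor node attributes.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edge_tsv", "graphml"),
                           ann = NULL) {
  stopifnot(inherits(net, "correlation_network"))
  format <- match.arg(format)
  if (format == "edge_tsv") {
    utils::write.table(as.data.frame(net), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    genera <- attr(net, "genera")
    flavors <- attr(net, "flavors")
    g <- igraph::graph_from_data_frame(
      net[, c("genus", "flavor")], directed = FALSE,
      vertices = data.frame(name = c(genera, flavors),
                            side = rep(c("genus", "flavor"),
                                       c(length(genera), length(flavors))),
                            stringsAsFactors = FALSE))
    if (!is.null(ann)) {
      ann <- validate_annotation(ann)
      m <- match(igraph::V(g)$name, ann$component_id)
      igraph::V(g)$kind <- ifelse(is.na(m), "", ann$kind[m])
      igraph::V(g)$category <- ifelse(is.na(m) | is.na(ann$category[m]),
                                      "", ann$category[m])
    }
    igraph::E(g)$r <- net$r
    igraph::E(g)$sign <- net$sign
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge TSV back into a `correlation_network`
#'
#' @param path file written by [export_network()] with `format =
#'   "edge_tsv"`.
#' @param threshold the threshold the network was built at (restored as an
#'   attribute; default: inferred as the largest conventional cutoff below
#'   the smallest `|r|`).
#' @param genera,flavors optional full node sets (defaults: nodes present
#'   in the edge list).
#' @return `correlation_network`.
#' @export
read_network <- function(path, threshold = NULL, genera = NULL,
                         flavors = NULL) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genus", "flavor", "r", "sign")
  if (!all(need %in% names(edges)))
    stop("edge file must have columns: ", paste(need, collapse = ", "))
  if (is.null(threshold)) {
    lo <- if (nrow(edges)) min(abs(edges$r)) else 1
    threshold <- max(c(0.5, 0.7, 0.8, 0.9)[c(0.5, 0.7, 0.8, 0.9) < lo], 0.5)
  }
  if (is.null(genera)) genera <- sort(unique(edges$genus))
  if (is.null(flavors)) flavors <- sort(unique(edges$flavor))
  edges <- edges[order(edges$genus, edges$flavor), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, class = c("correlation_network", "data.frame"),
            threshold = threshold, genera = genera, flavors = flavors)
}
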