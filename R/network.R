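# Undirected evidence edges (one row per study x comparison). Contrast
# studies contribute their explicit comparisons; arm-based studies a clique
# over their arms, as in the usual network diagram.
evidence_edges <- function(dataset) {
  stopifnot(inherits(dataset, "outcome_dataset"))
  ed <- NULL
  if (!is.null(dataset$contrasts)) {
    co <- dataset$contrasts
    ed <- data.frame(study = co$study,
                     t1 = pmin(co$reference, co$treatment),
                     t2 = pmax(co$reference, co$treatment))
  }
  if (!is.null(dataset$arms)) {
    for (s in unique(dataset$arms$study)) {
      tr <- sort(dataset$arms$treatment[dataset$arms$study == s])
      pr <- utils::combn(tr, 2)
      ed <- rbind(ed, data.frame(study = s, t1 = pr[1, ], t2 = pr[2, ]))
    }
  }
  unique(ed)
}

#' Build and validate the evidence network of a dataset
#'
#' Assembles the undirected multigraph whose nodes are treatments and whose
#' edges are observed head-to-head comparisons, and checks that it is
#' connected -- the condition under which indirect comparisons are defined.
#'
#' @param dataset An [outcome_dataset()].
#' @return An object of class `nma_network`: node list, per-edge study
#'   counts, and counts of nodes/edges/studies.
#' @export
build_network <- function(dataset) {
  ed <- evidence_edges(dataset)
  if (is.null(ed) || nrow(ed) == 0) stop("dataset has no evidence")
  nodes <- dataset$treatments$id
  g <- igraph::graph_from_data_frame(unique(ed[c("t1", "t2")]),
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    parts <- split(nodes, comp$membership)
    stop("evidence network is disconnected; components: ",
         paste(vapply(parts, function(p) paste0("{", paste(p, collapse = ", "), "}"),
                      ""), collapse = " "))
  }
  edges <- stats::aggregate(study ~ t1 + t2, data = ed,
                            FUN = function(s) paste(sort(unique(s)), collapse = "; "))
  names(edges)[names(edges) == "study"] <- "studies"
  edges$n_studies <- vapply(strsplit(edges$studies, "; ", fixed = TRUE),
                            length, 1L)
  edges <- edges[order(edges$t1, edges$t2), c("t1", "t2", "n_studies", "studies")]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 n_nodes = length(nodes), n_edges = nrow(edges),
                 n_studies = length(unique(ed$study)),
                 graph = g),
            class = "nma_network")
}

#' @export
print.nma_network <- function(x, ...) {
  cat("Connected evidence network:", x$n_nodes, "treatments,",
      x$n_edges, "direct comparisons,", x$n_studies, "studies\n")
  print(x$edges[c("t1", "t2", "n_studies")], row.names = FALSE)
  invisible(x)
}
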