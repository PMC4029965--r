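#' Build the signed bipartite CoMi network from a profile
#'
#' Keeps the indices with `p_value < alpha` (strict) as directed miRNA ->
#' term edges. Edge weight is `-log10(p)`; the edge's direction records
#' whether the miRNA's targets are up- or down-regulated relative to the
#' non-targets under the profiled condition.
#'
#' @param profile a [CoMiProfile-class].
#' @param alpha significance cutoff in (0, 1].
#' @return a [CoMiNetwork-class]; edges in the profile's deterministic order.
#' @export
buildNetwork <- function(profile, alpha = 0.05) {
  stopifnot(is(profile, "CoMiProfile"))
  if (!length(profile)) stop("empty profile")
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]")
  keep <- profile@pValue < alpha
  edges <- data.frame(
    mirna = profile@mirna[keep],
    term = profile@term[keep],
    statistic = profile@statistic[keep],
    p_value = profile@pValue[keep],
    weight = -log10(profile@pValue[keep]),
    direction = profile@direction[keep],
    stringsAsFactors = FALSE
  )
  new("CoMiNetwork", edges = edges, alpha = alpha)
}

#' Node degree table of a CoMi network
#'
#' miRNAs carry outgoing edges and terms incoming edges; the table reports
#' the out-degree of every miRNA node and the in-degree of every term node,
#' sorted by descending degree then lexicographically.
#'
#' @param net a [CoMiNetwork-class].
#' @return data.frame with columns `node`, `kind` ("mirna"/"term"),
#'   `degree`.
#' @export
degreeTable <- function(net) {
  stopifnot(is(net, "CoMiNetwork"))
  e <- net@edges
  if (!nrow(e))
    return(data.frame(node = character(0), kind = character(0),
                      degree = integer(0), stringsAsFactors = FALSE))
  out <- table(e$mirna)
  inn <- table(e$term)
  df <- rbind(
    data.frame(node = names(out), kind = "mirna",
               degree = as.integer(out), stringsAsFactors = FALSE),
    data.frame(node = names(inn), kind = "term",
               degree = as.integer(inn), stringsAsFactors = FALSE))
  df <- df[.ord(-df$degree, df$node), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Degree distribution histograms per network side
#'
#' @param net a [CoMiNetwork-class].
#' @return list with data.frames `mirna` and `term`, each with columns
#'   `degree` and `count` (exact node counts).
#' @export
degreeDistribution <- function(net) {
  dt <- degreeTable(net)
  hist1 <- function(kind) {
    d <- dt$degree[dt$kind == kind]
    if (!length(d))
      return(data.frame(degree = integer(0), count = integer(0)))
    tb <- table(d)
    data.frame(degree = as.integer(names(tb)), count = as.integer(tb))
  }
  list(mirna = hist1("mirna"), term = hist1("term"))
}

.NODE_PREFIX <- c(mirna = "mir:", term = "go:")

.netGraph <- function(net) {
  e <- net@edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0(.NODE_PREFIX[["mirna"]], e$mirna),
               to = paste0(.NODE_PREFIX[["term"]], e$term),
               statistic = e$statistic, p = e$p_value,
               weight = e$weight, direction = e$direction),
    directed = TRUE)
  igraph::V(g)$kind <- ifelse(startsWith(igraph::V(g)$name,
                                         .NODE_PREFIX[["mirna"]]),
                              "mirna", "term")
  g
}

#' Export a CoMi network
#'
#' GraphML carries node attribute `kind` (mirna/term) and edge attributes
#' statistic, p, weight, direction; node ids are namespaced (`mir:`/`go:`) so
#' a miRNA and a term can never collide. SIF writes one
#' `mirna regulates term` line per edge; TSV writes the flat edge list with
#' columns `mirna, term, statistic, p_value, weight, direction`.
#'
#' @param net a [CoMiNetwork-class].
#' @param path output path.
#' @param format one of `"graphml"`, `"sif"`, `"tsv"`.
#' @return `path`, invisibly.
#' @seealso [importNetwork()] for reloading a GraphML or TSV export.
#' @export
exportNetwork <- function(net, path, format = c("graphml", "sif", "tsv")) {
  stopifnot(is(net, "CoMiNetwork"))
  format <- match.arg(format)
  e <- net@edges
  if (format == "graphml") {
    igraph::write_graph(.netGraph(net), path, format = "graphml")
  } else if (format == "sif") {
    writeLines(paste(e$mirna, "regulates", e$term), path)
  } else {
    write.table(
      data.frame(mirna = e$mirna, term = e$term,
                 statistic = format(e$statistic, digits = 15, trim = TRUE,
                                    scientific = TRUE),
                 p_value = format(e$p_value, digits = 15, trim = TRUE,
                                  scientific = TRUE),
                 weight = format(e$weight, digits = 15, trim = TRUE,
                                 scientific = TRUE),
                 direction = e$direction),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Re-import an exported CoMi network
#'
#' @param path a GraphML or TSV file written by [exportNetwork()].
#' @param format `"graphml"` or `"tsv"`.
#' @param alpha the alpha the network was built with (edges are not
#'   re-thresholded).
#' @return a [CoMiNetwork-class].
#' @export
importNetwork <- function(path, format = c("graphml", "tsv"), alpha = 1) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    strip <- function(x, pre) substring(x, nchar(pre) + 1L)
    edges <- data.frame(
      mirna = strip(el$from, .NODE_PREFIX[["mirna"]]),
      term = strip(el$to, .NODE_PREFIX[["term"]]),
      statistic = el$statistic, p_value = el$p,
      weight = el$weight, direction = el$direction,
      stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    edges <- data.frame(
      mirna = as.character(df$mirna), term = as.character(df$term),
      statistic = as.numeric(df$statistic),
      p_value = as.numeric(df$p_value), weight = as.numeric(df$weight),
      direction = as.character(df$direction), stringsAsFactors = FALSE)
  }
  new("CoMiNetwork", edges = edges, alpha = alpha)
}
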