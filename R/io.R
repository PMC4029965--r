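PROFILE_FORMAT_TAG <- "comireg-profile\tv1"
PATTERNS_FORMAT_TAG <- "comireg-patterns\tv1"

#' Read a gene expression matrix from tab-delimited text
#'
#' Expects a header row of sample names and a first column of gene symbols;
#' the body must be numeric (log2-scale intensities). Duplicate gene rows are
#' collapsed by their arithmetic mean with a warning. Missing or non-finite
#' values are rejected.
#'
#' @param path path to a tab-delimited file.
#' @param labels optional named character vector mapping sample id to a
#'   condition tag; stored in `colData(x)$condition`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"exprs"` (genes x samples).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeExpression(matrix(1:6 / 2, 3, 2,
#'   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))), f)
#' se <- readExpression(f)
#' dim(se)
#' @export
readExpression <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", comment.char = "#")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty expression matrix in ", path)
  genes <- raw[[1]]
  body <- raw[-1]
  vals <- matrix(NA_real_, nrow(body), ncol(body),
                 dimnames = list(NULL, colnames(body)))
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric expression value at gene ", sQuote(genes[bad[1]]),
           ", sample ", sQuote(colnames(body)[j]))
    vals[, j] <- v
  }
  if (!all(is.finite(vals)))
    stop("non-finite expression values in ", path)
  if (anyDuplicated(genes)) {
    warning("collapsing ", sum(duplicated(genes)),
            " duplicate gene row(s) by mean")
    vals <- rowsum(vals, group = genes, reorder = FALSE)
    cnt <- as.vector(table(factor(genes, levels = unique(genes))))
    vals <- vals / cnt
    genes <- rownames(vals)
  }
  rownames(vals) <- genes
  if (anyDuplicated(colnames(vals))) stop("duplicate sample ids in ", path)
  cd <- S4Vectors::DataFrame(row.names = colnames(vals))
  if (!is.null(labels)) cd$condition <- unname(labels[colnames(vals)])
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = vals), colData = cd)
}

#' Write an expression matrix as tab-delimited text
#'
#' @param x a matrix or SummarizedExperiment (assay `"exprs"`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
  m <- .exprs(x)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## matrix view of an expression container
.exprs <- function(x) {
  if (is(x, "SummarizedExperiment"))
    return(SummarizedExperiment::assay(x, "exprs"))
  if (is.matrix(x)) return(x)
  stop("expected a matrix or SummarizedExperiment")
}

#' Read a gene set collection in GMT format
#'
#' Broad dialect: one set per line, tab-separated fields
#' `term_id TAB description TAB gene1 TAB gene2 ...`. Genes are deduplicated
#' within a set. An empty file yields an empty collection.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (one per term); each element
#'   carries its description in `attr(, "description")`.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT line ", i, " defines an empty set")
    s <- genes
    attr(s, "description") <- f[2]
    sets[[f[1]]] <- s
  }
  sets
}

#' Write a gene set collection in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA-to-target map from two-column tab-delimited text
#'
#' Each line holds `miRNA_id TAB gene_id`; duplicate lines collapse. An empty
#' file yields an empty map (downstream operations reject it explicitly).
#'
#' @param path path to the file.
#' @return named list: miRNA id -> character vector of target gene symbols.
#' @export
readTargetMap <- function(path) {
  if (!file.exists(path)) stop("target map not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop("target map line ", which(nf != 2L)[1], " does not have 2 fields")
  mir <- vapply(parts, `[[`, character(1), 1L)
  gene <- vapply(parts, `[[`, character(1), 2L)
  split(gene, mir) |> lapply(unique)
}

#' Write a target map as two-column tab-delimited text
#'
#' @param targets named list miRNA -> gene vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTargetMap <- function(targets, path) {
  mir <- rep(names(targets), lengths(targets))
  gene <- unlist(targets, use.names = FALSE)
  writeLines(paste(mir, gene, sep = "\t"), path)
  invisible(path)
}

#' Serialize / restore a CoMi profile
#'
#' Profiles round-trip through a single versioned tab-delimited file with
#' columns `mirna, term, n_T, n_NT, statistic, p_value, direction,
#' degenerate`; numeric fields are written to 15 significant digits so
#' `readProfile(writeProfile(x))` reproduces every field to at least 12
#' significant digits. A missing or mismatched version tag, or a truncated
#' body, is an error rather than a silent partial load.
#'
#' @param profile a [CoMiProfile-class].
#' @param path file path.
#' @param comment optional extra header lines (each prefixed with `"# "`).
#' @return `writeProfile`: `path` invisibly; `readProfile`: the profile.
#' @export
writeProfile <- function(profile, path, comment = character(0)) {
  stopifnot(is(profile, "CoMiProfile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", PROFILE_FORMAT_TAG), con)
  writeLines(paste0("# condition\t", profile@conditionId), con)
  writeLines(paste0("# nrows\t", length(profile)), con)
  for (cm in comment) writeLines(paste0("# ", cm), con)
  df <- data.frame(
    mirna = profile@mirna, term = profile@term,
    n_T = profile@nT, n_NT = profile@nNT,
    statistic = format(profile@statistic, digits = 15, scientific = TRUE,
                       trim = TRUE),
    p_value = format(profile@pValue, digits = 15, scientific = TRUE,
                     trim = TRUE),
    direction = profile@direction,
    degenerate = profile@degenerate
  )
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != paste0("# ", PROFILE_FORMAT_TAG))
    stop("not a comireg profile file (version tag mismatch): ", path)
  hdr <- grep("^#", lines, value = TRUE)
  cond <- sub("^# condition\t", "", grep("^# condition\t", hdr, value = TRUE))
  nrows <- as.integer(sub("^# nrows\t", "",
                          grep("^# nrows\t", hdr, value = TRUE)))
  if (length(cond) != 1L || length(nrows) != 1L)
    stop("malformed profile header in ", path)
  body <- lines[!grepl("^#", lines)]
  if (length(body) != nrows + 1L)
    stop("truncated profile file: expected ", nrows, " rows, found ",
         max(length(body) - 1L, 0L))
  df <- read.delim(text = body, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  newCoMiProfile(
    conditionId = cond, mirna = as.character(df$mirna),
    term = as.character(df$term), nT = as.integer(df$n_T),
    nNT = as.integer(df$n_NT), statistic = as.numeric(df$statistic),
    pValue = as.numeric(df$p_value), degenerate = as.logical(df$degenerate))
}

## internal constructor deriving direction from the statistic sign
newCoMiProfile <- function(conditionId, mirna, term, nT, nNT, statistic,
                           pValue, degenerate = logical(length(mirna))) {
  direction <- rep("null", length(mirna))
  direction[statistic > 0] <- "target_up"
  direction[statistic < 0] <- "target_down"
  new("CoMiProfile", conditionId = conditionId, mirna = mirna, term = term,
      nT = as.integer(nT), nNT = as.integer(nNT),
      statistic = as.numeric(statistic), pValue = as.numeric(pValue),
      direction = direction, degenerate = degenerate)
}

#' Serialize / restore a CoMi pattern set
#'
#' Patterns round-trip through a versioned tab-delimited file that includes
#' the frozen gene partitions (comma-separated), so profiles can be computed
#' from reloaded patterns.
#'
#' @param patterns a [CoMiPatternSet-class].
#' @param path file path.
#' @return `writePatterns`: `path` invisibly; `readPatterns`: the set.
#' @export
writePatterns <- function(patterns, path) {
  stopifnot(is(patterns, "CoMiPatternSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", PATTERNS_FORMAT_TAG), con)
  writeLines(paste0("# universe_size\t", patterns@universeSize), con)
  writeLines(paste0("# alpha\t",
                    format(patterns@alpha, digits = 15, trim = TRUE)), con)
  df <- data.frame(
    mirna = patterns@mirna, term = patterns@term,
    n_T = lengths(patterns@targetGenes),
    n_NT = lengths(patterns@nontargetGenes),
    overlap_p = format(patterns@overlapP, digits = 15, scientific = TRUE,
                       trim = TRUE),
    target_genes = vapply(patterns@targetGenes, paste, character(1),
                          collapse = ","),
    nontarget_genes = vapply(patterns@nontargetGenes, paste, character(1),
                             collapse = ",")
  )
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePatterns
#' @export
readPatterns <- function(path) {
  if (!file.exists(path)) stop("patterns file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != paste0("# ", PATTERNS_FORMAT_TAG))
    stop("not a comireg patterns file (version tag mismatch): ", path)
  hdr <- grep("^#", lines, value = TRUE)
  uni <- as.integer(sub("^# universe_size\t", "",
                        grep("^# universe_size\t", hdr, value = TRUE)))
  alpha <- as.numeric(sub("^# alpha\t", "",
                          grep("^# alpha\t", hdr, value = TRUE)))
  body <- lines[!grepl("^#", lines)]
  df <- read.delim(text = body, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  new("CoMiPatternSet",
      mirna = as.character(df$mirna), term = as.character(df$term),
      targetGenes = strsplit(as.character(df$target_genes), ",", fixed = TRUE),
      nontargetGenes = strsplit(as.character(df$nontarget_genes), ",",
                                fixed = TRUE),
      overlapP = as.numeric(df$overlap_p),
      universeSize = uni, alpha = alpha)
}

#' Read / write a patient cohort matrix
#'
#' The cohort file is features x samples, tab-delimited, with a leading
#' `label` row of 0/1 outcomes (1 = responder / pCR) and pattern keys as the
#' remaining row names.
#'
#' @param path file path.
#' @param cohort a SummarizedExperiment with assay `"comi"` and
#'   `colData()$label`.
#' @return `readCohort`: such a SummarizedExperiment; `writeCohort`: `path`.
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    comment.char = "#")
  feats <- as.character(raw[[1]])
  if (feats[1] != "label") stop("cohort file must start with a 'label' row")
  m <- as.matrix(raw[-1, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- feats[-1]
  labels <- as.integer(raw[1, -1])
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (!all(is.finite(m))) stop("non-finite cohort values in ", path)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(comi = m),
    colData = S4Vectors::DataFrame(label = labels,
                                   row.names = colnames(m)))
}

#' @rdname readCohort
#' @export
writeCohort <- function(cohort, path) {
  m <- SummarizedExperiment::assay(cohort, "comi")
  labels <- SummarizedExperiment::colData(cohort)$label
  df <- rbind(
    data.frame(feature = "label",
               matrix(as.numeric(labels), 1,
                      dimnames = list(NULL, colnames(m))),
               check.names = FALSE),
    data.frame(feature = rownames(m),
               format(m, digits = 15, scientific = TRUE, trim = TRUE),
               check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a drug library
#'
#' The manifest is tab-delimited with columns `instance_id, drug_name,
#' cell_line, concentration, is_positive, profile_path`; each profile path
#' (relative to the manifest's directory) is a serialized [CoMiProfile-class].
#'
#' @param path manifest path.
#' @param library a [DrugLibrary-class].
#' @param dir directory for the manifest and profile files.
#' @return `readDrugLibrary`: a DrugLibrary; `writeDrugLibrary`: the manifest
#'   path, invisibly.
#' @export
readDrugLibrary <- function(path) {
  if (!file.exists(path)) stop("library manifest not found: ", path)
  df <- read.delim(path, sep = "\t", check.names = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  base <- dirname(path)
  inst <- lapply(seq_len(nrow(df)), function(i) {
    new("DrugInstance",
        instanceId = as.character(df$instance_id[i]),
        drugName = as.character(df$drug_name[i]),
        cellLine = as.character(df$cell_line[i]),
        concentration = as.character(df$concentration[i]),
        profile = readProfile(file.path(base, df$profile_path[i])),
        isPositive = as.logical(df$is_positive[i]))
  })
  new("DrugLibrary", instances = inst)
}

#' @rdname readDrugLibrary
#' @export
writeDrugLibrary <- function(library, dir) {
  stopifnot(is(library, "DrugLibrary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(library@instances, function(inst) {
    pfile <- paste0(inst@instanceId, ".profile.tsv")
    writeProfile(inst@profile, file.path(dir, pfile))
    data.frame(instance_id = inst@instanceId, drug_name = inst@drugName,
               cell_line = inst@cellLine, concentration = inst@concentration,
               is_positive = inst@isPositive, profile_path = pfile)
  })
  manifest <- file.path(dir, "library.tsv")
  write.table(do.call(rbind, rows), manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest)
}

#' Read sample metadata (sample id, label)
#'
#' @param path two-column tab-delimited file with a header.
#' @return named character vector: sample id -> label.
#' @export
readSampleLabels <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("metadata needs two columns (sample_id, label)")
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}
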