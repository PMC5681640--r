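#' Read an expression matrix from TSV
#'
#' First column is the feature id, header row holds sample ids. Duplicate
#' sample columns and duplicate feature rows are averaged; values must be
#' non-negative and finite.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix (features x samples).
#' @export
read_expression <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  raw <- utils::read.delim(path, header = FALSE, skip = 1L,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L || length(hdr) != ncol(raw)) {
    stop("expression file is empty or malformed: ", path)
  }
  feats <- as.character(raw[[1L]])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(raw[-1L], is.numeric, logical(1L)))[1L]
    stop(sprintf("non-numeric expression values in column '%s' of %s",
                 hdr[-1L][bad], path))
  }
  # assign sample ids ourselves: read.delim mangles duplicated header names
  dimnames(vals) <- list(feats, hdr[-1L])
  # duplicate samples: average columns sharing an id
  if (anyDuplicated(colnames(vals))) {
    vals <- vapply(unique(colnames(vals)), function(s) {
      rowMeans(vals[, colnames(vals) == s, drop = FALSE])
    }, numeric(nrow(vals)))
  }
  # duplicate features: average rows sharing an id
  if (anyDuplicated(rownames(vals))) {
    vals <- t(vapply(unique(rownames(vals)), function(f) {
      colMeans(vals[rownames(vals) == f, , drop = FALSE])
    }, numeric(ncol(vals))))
  }
  assert_expression_matrix(vals, path)
  vals
}

#' Write an expression matrix (or activity profile) to TSV
#'
#' @param mat Matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @param id_column Name of the first column (default `"feature_id"`).
#' @export
write_expression <- function(mat, path, id_column = "feature_id") {
  df <- data.frame(rownames(mat), unclass(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a clinical survival table from TSV
#'
#' Requires columns `sample_id`, `time`, `event`; any further columns are
#' carried along as covariates. Samples with survival time strictly below
#' `min_survival` are excluded (the count is reported via a message), since
#' very early deaths are likely unrelated to the disease under study.
#'
#' @param path Path to a TSV file.
#' @param min_survival Exclusion threshold on survival time, in the same
#'   unit as the `time` column (default 30, i.e. days for daily times).
#' @return Data frame (`sample_id`, `time`, `event`, covariates).
#' @export
read_clinical <- function(path, min_survival = 30) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("sample_id", "time", "event")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("clinical file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  drop <- df$time < min_survival
  if (any(drop)) {
    message(sprintf("excluded %d sample(s) with survival time < %s",
                    sum(drop), format(min_survival)))
    df <- df[!drop, , drop = FALSE]
  }
  rownames(df) <- NULL
  assert_survival_table(df)
  df
}

#' Write a clinical survival table to TSV
#' @param survival Survival table data frame.
#' @param path Output path.
#' @export
write_clinical <- function(survival, path) {
  utils::write.table(survival, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read pathway graphs from a TSV edge list
#'
#' Expects columns `pathway_id`, `gene_a`, `gene_b`; one graph per distinct
#' pathway id. An optional node file (`pathway_id`, `gene_id`) supplies
#' isolated genes.
#'
#' @param path Edge-list TSV path.
#' @param node_path Optional node-list TSV path.
#' @return List of [pathway_graph()] objects, in first-appearance order.
#' @export
read_pathways <- function(path, node_path = NULL) {
  e <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("pathway_id", "gene_a", "gene_b")
  if (!all(req %in% names(e))) {
    stop("pathway file must have columns: ", paste(req, collapse = ", "))
  }
  nodes <- NULL
  if (!is.null(node_path)) {
    nodes <- utils::read.delim(node_path, header = TRUE,
                               stringsAsFactors = FALSE)
    if (!all(c("pathway_id", "gene_id") %in% names(nodes))) {
      stop("node file must have columns: pathway_id, gene_id")
    }
  }
  ids <- unique(c(e$pathway_id, nodes$pathway_id))
  lapply(ids, function(pid) {
    sub <- e[e$pathway_id == pid, c("gene_a", "gene_b"), drop = FALSE]
    extra <- if (!is.null(nodes)) nodes$gene_id[nodes$pathway_id == pid]
    pathway_graph(pid, as.matrix(sub), nodes = extra)
  })
}

#' Write pathway graphs to a TSV edge list
#' @param pathways List of [pathway_graph()] objects.
#' @param path Output path.
#' @export
write_pathways <- function(pathways, path) {
  rows <- do.call(rbind, lapply(pathways, function(pw) {
    if (nrow(pw$edges) == 0L) return(NULL)
    data.frame(pathway_id = pw$pathway_id, gene_a = pw$edges[, 1L],
               gene_b = pw$edges[, 2L], stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-target interaction table from TSV
#'
#' Expects columns `mirna_id`, `gene_id`, `evidence` (values `low`/`high`).
#'
#' @param path TSV path.
#' @return A [mirna_target_table()].
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("mirna_id", "gene_id", "evidence")
  if (!all(req %in% names(df))) {
    stop("interaction file must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(df$evidence %in% c("low", "high"))) {
    stop("'evidence' must be 'low' or 'high'")
  }
  mirna_target_table(df$mirna_id, df$gene_id, df$evidence == "low")
}

#' Write a miRNA-target interaction table to TSV
#' @param interactions A [mirna_target_table()].
#' @param path Output path.
#' @export
write_interactions <- function(interactions, path) {
  df <- data.frame(mirna_id = interactions$mirna_id,
                   gene_id = interactions$gene_id,
                   evidence = ifelse(interactions$low_throughput,
                                     "low", "high"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write subpathways as SIF and GMT files
#'
#' The SIF file lists one edge per line (`node_a`, interaction type
#' `gene-gene` or `mirna-gene`, `node_b`); the GMT file lists one
#' subpathway per line with tab-separated member ids prefixed `g:` (genes)
#' and `m:` (miRNAs).
#'
#' @param subpathways List of [subpathway_graph()] objects.
#' @param sif_path,gmt_path Output paths; either may be `NULL` to skip.
#' @export
write_subpathways <- function(subpathways, sif_path = NULL, gmt_path = NULL) {
  if (!is.null(sif_path)) {
    lines <- as.character(unlist(lapply(subpathways, function(s) {
      c(if (nrow(s$gene_edges) > 0L)
          paste(s$gene_edges[, 1L], "gene-gene", s$gene_edges[, 2L],
                sep = "\t"),
        if (nrow(s$mirna_edges) > 0L)
          paste(s$mirna_edges$mirna_id, "mirna-gene",
                s$mirna_edges$gene_id, sep = "\t"))
    })))
    writeLines(lines, sif_path)
  }
  if (!is.null(gmt_path)) {
    lines <- vapply(subpathways, function(s) {
      paste(c(s$subpathway_id,
              paste0("parent=", s$parent_pathway_id),
              paste0("g:", s$gene_nodes), paste0("m:", s$mirna_nodes)),
            collapse = "\t")
    }, character(1L))
    writeLines(lines, gmt_path)
  }
  invisible(NULL)
}

#' Read subpathway memberships from a GMT file
#'
#' Reads the membership dialect written by [write_subpathways()]: members
#' are prefixed `g:` / `m:`. Gene-gene and miRNA-gene edges are not stored
#' in GMT and come back empty; scoring only needs memberships.
#'
#' @param path GMT path.
#' @return List of [subpathway_graph()] objects.
#' @export
read_subpathways <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(ln, 1, 60))
    parent <- sub("^parent=", "", parts[2L])
    members <- parts[-(1:2)]
    subpathway_graph(
      subpathway_id = parts[1L], parent_pathway_id = parent,
      gene_nodes = sub("^g:", "", members[startsWith(members, "g:")]),
      mirna_nodes = sub("^m:", "", members[startsWith(members, "m:")])
    )
  })
}

#' Read an activity profile from TSV
#' @param path TSV path (first column subpathway id, `NA` for missing).
#' @param level Level tag to attach.
#' @return An `activity_profile`.
#' @export
read_profile <- function(path, level = "integrated") {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(m) <- as.character(raw[[1L]])
  activity_profile(m, level = level)
}

#' Write an activity profile to TSV
#' @param profile An `activity_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  write_expression(unclass(profile), path, id_column = "subpathway_id")
}
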