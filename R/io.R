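# Plain-text readers/writers for graphs, memberships, and datasets.

#' Write a binary graph as a whitespace-delimited edge list
#'
#' Node ids are 0-based; one undirected edge per line (`i j` with `i < j`).
#'
#' @param graph An [fc_graph()] or adjacency matrix.
#' @param path Output file.
#' @export
write_edge_list <- function(graph, path) {
  adj <- .as_adjacency(graph)
  ed <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  utils::write.table(ed - 1L, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path Input file.
#' @param n_nodes Total node count (isolated nodes are not represented in the
#'   edge list).
#' @return An [fc_graph()].
#' @export
read_edge_list <- function(path, n_nodes) {
  ed <- as.matrix(utils::read.table(path)) + 1L
  adj <- matrix(0L, n_nodes, n_nodes)
  adj[ed] <- 1L
  adj[ed[, c(2, 1), drop = FALSE]] <- 1L
  fc_graph(adj)
}

#' Write a membership matrix as a delimited node-by-community table
#'
#' @param pi Node-by-k membership matrix.
#' @param path Output file.
#' @param level,condition,seed Optional metadata written into the header
#'   comment line.
#' @export
write_membership <- function(pi, path, level = NULL, condition = NULL, seed = NULL) {
  meta <- c(level = level, condition = condition, seed = seed,
            k = ncol(pi))
  writeLines(paste0("# ", paste(names(meta), unlist(meta), sep = "=", collapse = " ")),
             path)
  df <- data.frame(node = seq_len(nrow(pi)) - 1L, pi)
  names(df) <- c("node", paste0("community_", seq_len(ncol(pi))))
  suppressWarnings(utils::write.table(df, path, append = TRUE, sep = "\t",
                                      row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Read a membership table written by [write_membership()]
#'
#' @param path Input file.
#' @return The membership matrix (metadata in attribute `"meta"`).
#' @export
read_membership <- function(path) {
  meta <- sub("^# ", "", readLines(path, n = 1))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  pi <- as.matrix(df[, -1, drop = FALSE])
  dimnames(pi) <- NULL
  attr(pi, "meta") <- meta
  pi
}

#' Write ground-truth memberships of a benchmark graph
#'
#' Long format: one `(node, community, membership)` row per nonzero
#' affiliation, 0-based node ids.
#'
#' @param truth Node-by-community (binary or simplex) truth matrix.
#' @param path Output file.
#' @export
write_truth_table <- function(truth, path) {
  nz <- which(truth > 0, arr.ind = TRUE)
  df <- data.frame(node = nz[, 1] - 1L, community = nz[, 2],
                   membership = truth[nz])
  utils::write.table(df[order(df$node, df$community), ], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a hierarchical dataset as a directory tree with a manifest
#'
#' One delimited ROI-by-time matrix per run under
#' `dir/animal/session/run.tsv`, plus `manifest.tsv` recording metadata and
#' the generator seed.
#'
#' @param dataset An [fc_dataset()].
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "fc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset$runs, function(r) {
    rel <- file.path(r$animal_id, r$session_id, paste0(r$run_id, ".tsv"))
    dir.create(dirname(file.path(dir, rel)), recursive = TRUE, showWarnings = FALSE)
    utils::write.table(r$signal, file.path(dir, rel), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    if (!is.null(r$motion)) {
      utils::write.table(data.frame(motion = r$motion),
                         file.path(dir, sub("\\.tsv$", "_motion.tsv", rel)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    data.frame(animal = r$animal_id, session = r$session_id, run = r$run_id,
               condition = r$condition, fs = r$fs, path = rel,
               has_motion = !is.null(r$motion))
  })
  manifest <- do.call(rbind, rows)
  manifest$seed <- dataset$seed %||% NA
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory containing `manifest.tsv`.
#' @return An [fc_dataset()].
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  runs <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    sig <- as.matrix(utils::read.table(file.path(dir, m$path), sep = "\t"))
    dimnames(sig) <- NULL
    motion <- NULL
    if (isTRUE(m$has_motion)) {
      motion <- utils::read.table(file.path(dir, sub("\\.tsv$", "_motion.tsv", m$path)),
                                  header = TRUE, sep = "\t")$motion
    }
    run_record(sig, fs = m$fs, animal_id = m$animal, session_id = m$session,
               run_id = m$run, condition = m$condition, motion = motion)
  })
  seed <- manifest$seed[1]
  fc_dataset(runs, seed = if (is.na(seed)) NULL else seed)
}

#' Write a gradient set with an eigenvalue header block
#'
#' @param gradients A `"gradient_set"`.
#' @param path Output file.
#' @export
write_gradients <- function(gradients, path) {
  stopifnot(inherits(gradients, "gradient_set"))
  hdr <- c(paste("# eigenvalues", paste(gradients$eigenvalues, collapse = " ")),
           paste("# variance_fraction", paste(gradients$variance_fraction, collapse = " ")))
  writeLines(hdr, path)
  df <- data.frame(node = seq_len(nrow(gradients$components)) - 1L,
                   gradients$components)
  names(df) <- c("node", paste0("G", seq_len(ncol(gradients$components))))
  suppressWarnings(utils::write.table(df, path, append = TRUE, sep = "\t",
                                      row.names = FALSE, quote = FALSE))
  invisible(path)
}
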