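# Signature molecular descriptor: counts of canonical atom-rooted fragments
# at heights 1-3. For each heavy atom and height h, the induced subgraph of
# atoms within h bonds of the root is encoded as the lexicographically
# minimal depth-first traversal string of the rooted graph — atom token =
# element symbol + formal charge sign, bond tokens -, =, #, : , ring
# closures as back-references to the visit position — which is invariant
# under any relabelling of the molecule's atom indices.

.atom_token <- function(elem, charge) {
  suff <- ifelse(charge == 0L, "",
                 ifelse(charge == 1L, "+", ifelse(charge == -1L, "-",
                        sprintf("%+d", charge))))
  paste0(elem, suff)
}

.bond_token <- c(`1` = "-", `2` = "=", `3` = "#", `4` = ":")

# Lexicographically minimal rooted DFS string of a small connected graph.
# States are (string, visited, pos, used, stack); at each step the current
# vertex is the top of the stack, choices are its unused edges, exhausting
# them pops the stack and emits ")". The global lexicographic minimum over
# completed traversals is the canonical string; fragments are small (tens
# of atoms at height 3) so the pruned search space is tiny in practice.
.canon_rooted_min <- function(atom_tok, adj, root) {
  n_edges <- sum(vapply(adj, function(m) if (is.null(m)) 0L else nrow(m), integer(1))) / 2
  best <- NULL

  explore <- function(acc, visited, pos, used, stack) {
    if (!is.null(best)) {
      cmp <- substr(best, 1, nchar(acc))
      if (acc > cmp) return(invisible())
    }
    if (length(stack) == 0) {
      if (is.null(best) || acc < best) best <<- acc
      return(invisible())
    }
    v <- stack[[length(stack)]]
    nb <- adj[[v]]
    cand <- list()
    if (!is.null(nb) && nrow(nb) > 0) {
      for (k in seq_len(nrow(nb))) {
        u <- as.integer(nb[k, 1])
        ek <- if (v < u) paste0(v, ".", u) else paste0(u, ".", v)
        if (!isTRUE(used[[ek]])) cand[[length(cand) + 1]] <- list(u = u, bt = nb[k, 2], ek = ek)
      }
    }
    if (length(cand) == 0) {
      # backtrack from v
      close <- if (length(stack) > 1) ")" else ""
      explore(paste0(acc, close), visited, pos, used, stack[-length(stack)])
      return(invisible())
    }
    # deduplicate identical immediate choices to curb branching: two edges
    # with the same bond token to unvisited atoms with the same atom token
    # still differ in their subtrees, so branch over all of them; but prune
    # by trying in sorted order so good prefixes are found early.
    ord <- order(vapply(cand, function(cc) {
      if (visited[cc$u]) paste0("[", cc$bt, pos[cc$u], "]")
      else paste0("(", cc$bt, atom_tok[cc$u])
    }, character(1)))
    for (k in ord) {
      cc <- cand[[k]]
      used2 <- used; used2[[cc$ek]] <- TRUE
      if (visited[cc$u]) {
        explore(paste0(acc, "[", cc$bt, pos[cc$u], "]"), visited, pos, used2, stack)
      } else {
        visited2 <- visited; visited2[cc$u] <- TRUE
        pos2 <- pos; pos2[cc$u] <- sum(visited) + 1L
        explore(paste0(acc, "(", cc$bt, atom_tok[cc$u]),
                visited2, pos2, used2, c(stack, cc$u))
      }
    }
    invisible()
  }

  visited <- logical(length(atom_tok)); visited[root] <- TRUE
  pos <- integer(length(atom_tok)); pos[root] <- 1L
  explore(atom_tok[root], visited, pos, list(), list(root))
  best
}

# canonical string of the height-h fragment rooted at `root`
.fragment_canon <- function(g, root, h) {
  # BFS distances from root
  dist <- rep(NA_integer_, g$n); dist[root] <- 0L
  frontier <- root
  adj_idx <- vector("list", g$n)
  if (nrow(g$bonds) > 0)
    for (b in seq_len(nrow(g$bonds))) {
      adj_idx[[g$bonds[b, 1]]] <- c(adj_idx[[g$bonds[b, 1]]], b)
      adj_idx[[g$bonds[b, 2]]] <- c(adj_idx[[g$bonds[b, 2]]], b)
    }
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      if (dist[v] >= h) next
      for (b in adj_idx[[v]]) {
        u <- if (g$bonds[b, 1] == v) g$bonds[b, 2] else g$bonds[b, 1]
        if (is.na(dist[u])) { dist[u] <- dist[v] + 1L; nxt <- c(nxt, u) }
      }
    }
    frontier <- nxt
  }
  keep <- which(!is.na(dist) & dist <= h)
  old2new <- match(seq_len(g$n), keep)
  tok <- .atom_token(g$elem[keep], g$charge[keep])
  adj <- vector("list", length(keep))
  if (nrow(g$bonds) > 0)
    for (b in seq_len(nrow(g$bonds))) {
      a1 <- old2new[g$bonds[b, 1]]; a2 <- old2new[g$bonds[b, 2]]
      if (is.na(a1) || is.na(a2)) next
      bt <- .bond_token[as.character(g$bonds[b, 3])]
      if (is.na(bt)) bt <- "-"
      adj[[a1]] <- rbind(adj[[a1]], c(a2, bt))
      adj[[a2]] <- rbind(adj[[a2]], c(a1, bt))
    }
  .canon_rooted_min(tok, adj, old2new[root])
}

#' Enumerate signature fragments of a molecule
#'
#' For every heavy atom and every requested height, the induced subgraph of
#' atoms within that many bonds of the root is canonically encoded; the
#' result maps each distinct key to its occurrence count. Per height, the
#' counts sum to the heavy-atom count (one rooted fragment per atom).
#'
#' @param x A \code{ChemmineR::SDF} object or a \code{\link{molecule_graph}}
#'   list.
#' @param heights Integer vector of fragment heights (default \code{1:3}).
#' @return Named integer vector; names are keys of the form
#'   \code{"h<height>|<canonical string>"}.
#' @export
enumerate_signatures <- function(x, heights = 1:3) {
  g <- if (methods::is(x, "SDF")) molecule_graph(x) else x
  stopifnot(is.list(g), all(c("elem", "charge", "bonds", "n") %in% names(g)))
  if (g$n == 0) return(structure(integer(0), names = character(0)))
  keys <- unlist(lapply(heights, function(h)
    vapply(seq_len(g$n), function(r)
      paste0("h", h, "|", .fragment_canon(g, r, h)), character(1))))
  tab <- table(keys)
  structure(as.integer(tab), names = names(tab))
}

#' Apply a random atom relabelling to a molecule graph
#'
#' Test utility: permutes atom indices; \code{\link{enumerate_signatures}}
#' must be invariant under any such relabelling.
#'
#' @param g A \code{\link{molecule_graph}} list.
#' @param perm A permutation of \code{1:g$n}; \code{perm[i]} is the new
#'   index of old atom \code{i}.
#' @return The relabelled graph.
#' @export
permute_graph <- function(g, perm) {
  stopifnot(length(perm) == g$n, all(sort(perm) == seq_len(g$n)))
  inv <- order(perm)
  bonds <- g$bonds
  if (nrow(bonds) > 0) {
    bonds[, 1] <- perm[bonds[, 1]]
    bonds[, 2] <- perm[bonds[, 2]]
  }
  list(elem = g$elem[inv], charge = g$charge[inv], bonds = bonds, n = g$n)
}

#' Build the fragment vocabulary of a training set
#'
#' The union of all signature keys over the training molecules, ordered
#' deterministically (lexicographically, i.e. by height then canonical
#' string). Feature matrices for later batches are restricted to this
#' training vocabulary.
#'
#' @param molecules A list of \code{SDF} objects or molecule graphs.
#' @param heights Fragment heights (default \code{1:3}).
#' @return Character vector of signature keys.
#' @export
build_vocabulary <- function(molecules, heights = 1:3) {
  keys <- unique(unlist(lapply(molecules, function(m)
    names(enumerate_signatures(m, heights)))))
  if (is.null(keys)) return(character(0))
  sort(keys, method = "radix")
}

#' Sparse signature count matrix over a fixed vocabulary
#'
#' Fragments absent from the vocabulary are silently dropped (the
#' training-vocabulary restriction); a molecule sharing no fragment with the
#' vocabulary yields an all-zero row, which is kept and reported via a
#' message.
#'
#' @param molecules List of \code{SDF} objects or molecule graphs.
#' @param vocabulary Character vector from \code{\link{build_vocabulary}}.
#' @param heights Fragment heights (default \code{1:3}).
#' @param row_ids Optional molecule identifiers (default \code{mol<i>}).
#' @return A list of class \code{signature_matrix}: \code{counts}
#'   (\code{Matrix::dgCMatrix}), \code{vocabulary}, \code{row_ids}.
#' @export
featurise <- function(molecules, vocabulary, heights = 1:3, row_ids = NULL) {
  n <- length(molecules)
  if (is.null(row_ids)) row_ids <- sprintf("mol%d", seq_len(n))
  stopifnot(length(row_ids) == n, !anyDuplicated(vocabulary))
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  n_zero <- 0L
  for (i in seq_len(n)) {
    sig <- enumerate_signatures(molecules[[i]], heights)
    j <- match(names(sig), vocabulary)
    keep <- !is.na(j)
    if (!any(keep) && length(vocabulary) > 0) n_zero <- n_zero + 1L
    ii <- c(ii, rep(i, sum(keep))); jj <- c(jj, j[keep]); xx <- c(xx, sig[keep])
  }
  if (n_zero > 0)
    message(n_zero, " molecule(s) share no fragment with the vocabulary (all-zero rows kept)")
  counts <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(xx),
                                 dims = c(n, length(vocabulary)),
                                 dimnames = list(row_ids, NULL))
  structure(list(counts = counts, vocabulary = vocabulary, row_ids = row_ids),
            class = "signature_matrix")
}

#' Write / read a signature matrix in MatrixMarket layout
#'
#' The on-disk layout mirrors published sparse-fingerprint distributions:
#' a MatrixMarket \code{.mtx} count matrix plus sidecar text files holding
#' the vocabulary (one canonical string per line) and the row identifiers.
#' \code{read_signature_matrix} therefore also ingests such pre-computed
#' fingerprint sets directly.
#'
#' @param sm A \code{signature_matrix} (or any list with \code{counts},
#'   \code{vocabulary}, \code{row_ids}).
#' @param dir Directory for \code{counts.mtx}, \code{vocabulary.txt},
#'   \code{row_ids.txt}.
#' @return The directory (write) or a \code{signature_matrix} (read).
#' @export
write_signature_matrix <- function(sm, dir) {
  stopifnot(all(c("counts", "vocabulary", "row_ids") %in% names(sm)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(sm$counts, "CsparseMatrix"), file.path(dir, "counts.mtx"))
  writeLines(sm$vocabulary, file.path(dir, "vocabulary.txt"))
  writeLines(sm$row_ids, file.path(dir, "row_ids.txt"))
  invisible(dir)
}

#' @rdname write_signature_matrix
#' @export
read_signature_matrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")), "CsparseMatrix")
  vocabulary <- readLines(file.path(dir, "vocabulary.txt"))
  row_ids <- readLines(file.path(dir, "row_ids.txt"))
  stopifnot(nrow(counts) == length(row_ids), ncol(counts) == length(vocabulary))
  dimnames(counts) <- list(row_ids, NULL)
  structure(list(counts = counts, vocabulary = vocabulary, row_ids = row_ids),
            class = "signature_matrix")
}
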