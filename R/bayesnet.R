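#' Discretize normalized expression at the per-miRNA median
#'
#' A specimen is "high" for a miRNA when its normalized value is greater
#' than or equal to that miRNA's median across specimens (median of an even
#' number of values is the midpoint of the two central order statistics);
#' otherwise "low".
#'
#' @param norm `ev_norm` or normalized matrix (miRNA x specimen).
#' @return data.frame of factors (levels low/high), rows = specimens,
#'   columns = miRNAs.
#' @export
discretize_by_median <- function(norm) {
  x <- norm_values(norm)
  if (ncol(x) < 2L) stop("need >= 2 specimens")
  med <- apply(x, 1, stats::median)
  out <- as.data.frame(lapply(seq_len(nrow(x)), function(i) {
    factor(ifelse(x[i, ] >= med[i], "high", "low"),
           levels = c("low", "high"))
  }), optional = TRUE)
  names(out) <- rownames(x)
  rownames(out) <- colnames(x)
  out
}

#' Append pathology indicator nodes
#'
#' Adds three binary variables describing specimen pathology: `cancer`
#' (PDAC), `pancreatitis` (CP), and `metastasis` (metastatic PDAC only).
#'
#' @param data discrete dataset from [discretize_by_median()] (rows named
#'   by specimen).
#' @param samples metadata with specimen_id, diagnosis, metastasis.
#' @return the dataset with the three indicator columns appended.
#' @export
add_pathology_nodes <- function(data, samples) {
  idx <- match(rownames(data), samples$specimen_id)
  if (anyNA(idx)) stop("specimens missing from the metadata table")
  diag <- samples$diagnosis[idx]
  bad <- !diag %in% c("PDAC", "CP", "healthy")
  if (any(bad))
    stop("unknown diagnosis for specimen(s): ",
         paste(rownames(data)[bad], collapse = ", "))
  tf <- function(x) factor(ifelse(x, "true", "false"),
                           levels = c("false", "true"))
  data$cancer <- tf(diag == "PDAC")
  data$pancreatitis <- tf(diag == "CP")
  m1 <- !is.na(samples$metastasis[idx]) & samples$metastasis[idx] == "M1"
  data$metastasis <- tf(diag == "PDAC" & m1)
  data
}

# internal representation: integer matrix (1..r per column) + level counts
as_discrete_int <- function(data) {
  stopifnot(is.data.frame(data), nrow(data) >= 1L)
  m <- vapply(data, function(col) as.integer(as.factor(col)),
              integer(nrow(data)))
  if (anyNA(m)) stop("discrete data must have no missing values")
  nlev <- vapply(data, function(col) length(levels(as.factor(col))),
                 integer(1))
  list(m = matrix(m, nrow = nrow(data),
                  dimnames = list(NULL, names(data))),
       nlev = stats::setNames(nlev, names(data)))
}

#' BIC score of one node given a parent set
#'
#' Multinomial log-likelihood of the child given each parent configuration,
#' minus the penalty `0.5 * log(n) * (r - 1) * q`, where r is the child's
#' state count and q the number of parent configurations (product of
#' parent state counts). Zero-count cells contribute 0 (0*log 0 = 0). The
#' empty parent set reduces to the marginal multinomial term.
#'
#' @param child column name of the child variable.
#' @param parent_set character vector of parent column names (may be
#'   empty); must not contain the child.
#' @param data discrete data.frame of factors.
#' @return the BIC family score (higher is better).
#' @export
bic_family_score <- function(child, parent_set, data) {
  if (child %in% parent_set) stop("child cannot be its own parent")
  d <- as_discrete_int(data)
  bic_family_score_int(match(child, colnames(d$m)),
                       match(parent_set, colnames(d$m)), d)
}

bic_family_score_int <- function(ci, pi, d) {
  n <- nrow(d$m)
  r <- d$nlev[ci]
  child <- d$m[, ci]
  if (length(pi) == 0L) {
    cfg <- rep(1L, n); q <- 1L
  } else {
    q <- prod(d$nlev[pi])
    cfg <- rep(1L, n); mult <- 1L
    for (k in pi) {
      cfg <- cfg + (d$m[, k] - 1L) * mult
      mult <- mult * d$nlev[k]
    }
  }
  idx <- (cfg - 1L) * r + child
  njk <- tabulate(idx, nbins = q * r)
  nj <- tabulate(cfg, nbins = q)
  nz <- njk > 0
  ll <- sum(njk[nz] * log(njk[nz] / nj[ceiling(which(nz) / r)]))
  as.numeric(ll - 0.5 * log(n) * (r - 1) * q)
}

new_dag <- function(nodes, parents = NULL, score = NA_real_,
                    family_scores = NULL) {
  if (is.null(parents))
    parents <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  structure(list(nodes = nodes, parents = parents, score = score,
                 family_scores = family_scores), class = "ev_dag")
}

#' Edge list of a DAG
#'
#' @param dag an `ev_dag`.
#' @return data.frame with columns from, to (one row per directed edge).
#' @export
dag_edges <- function(dag) {
  e <- do.call(rbind, lapply(dag$nodes, function(j) {
    p <- dag$parents[[j]]
    if (length(p)) data.frame(from = p, to = j, stringsAsFactors = FALSE)
  }))
  if (is.null(e)) data.frame(from = character(0), to = character(0)) else
    e[order(e$from, e$to), , drop = FALSE]
}

#' @export
print.ev_dag <- function(x, ...) {
  cat(sprintf("DAG: %d nodes, %d edges, score %.4f\n", length(x$nodes),
              nrow(dag_edges(x)), x$score))
  invisible(x)
}

# is there a directed path from `from` to `to` given parents lists?
has_path <- function(parents, from, to) {
  # children adjacency
  stack <- from
  seen <- character(0)
  children <- function(v)
    names(parents)[vapply(parents, function(p) v %in% p, logical(1))]
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v == to) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, children(v))
  }
  FALSE
}

#' Score-based DAG structure learning by tabu search
#'
#' Greedy hill climbing over single-edge additions, deletions and
#' reversals maximizing the total BIC, with a tabu list of the most
#' recently undone moves and a patience budget of non-improving moves to
#' escape local optima. Acyclicity is preserved at every step. The search
#' is deterministic given the data and the lexicographic tie-break on
#' moves; `seed` is accepted for interface stability.
#'
#' @param data discrete data.frame of factors (rows = observations).
#' @param max_iter maximum number of accepted moves (> 0).
#' @param tabu_len length of the tabu move list.
#' @param patience accepted non-improving moves before stopping.
#' @param seed unused by the deterministic search; kept for reproducible
#'   call signatures.
#' @return the best-scoring `ev_dag` visited.
#' @export
tabu_search <- function(data, max_iter = 10000, tabu_len = 10,
                        patience = 10, seed = 1L) {
  if (max_iter <= 0) stop("max_iter must be > 0")
  d <- as_discrete_int(data)
  nodes <- colnames(d$m)
  p <- length(nodes)
  idx <- stats::setNames(seq_len(p), nodes)
  cache <- new.env(parent = emptyenv())
  fam <- function(child, parents) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- bic_family_score_int(idx[[child]], idx[parents], d)
    cache[[key]]
  }
  parents <- stats::setNames(rep(list(character(0)), p), nodes)
  fs <- stats::setNames(vapply(nodes, function(j) fam(j, character(0)),
                               numeric(1)), nodes)
  total <- sum(fs)
  best_parents <- parents; best_score <- total
  tabu <- character(0)
  move_key <- function(op, a, b) paste(op, a, b, sep = "|")

  propose <- function() {
    # enumerate admissible moves with deltas; lexicographic order built in
    moves <- list()
    for (a in nodes) for (b in nodes) {
      if (a == b) next
      if (a %in% parents[[b]]) {
        # delete a -> b
        moves[[length(moves) + 1L]] <-
          list(op = "del", a = a, b = b,
               delta = fam(b, setdiff(parents[[b]], a)) - fs[[b]])
        # reverse a -> b (needs no other path a ~> b after removal)
        pa2 <- setdiff(parents[[b]], a)
        tmp <- parents; tmp[[b]] <- pa2
        if (!has_path(tmp, a, b) && !(b %in% parents[[a]])) {
          moves[[length(moves) + 1L]] <-
            list(op = "rev", a = a, b = b,
                 delta = (fam(b, pa2) - fs[[b]]) +
                   (fam(a, c(parents[[a]], b)) - fs[[a]]))
        }
      } else if (!(b %in% parents[[a]])) {
        # add a -> b if acyclic
        if (!has_path(parents, b, a)) {
          moves[[length(moves) + 1L]] <-
            list(op = "add", a = a, b = b,
                 delta = fam(b, c(parents[[b]], a)) - fs[[b]])
        }
      }
    }
    moves
  }

  no_improve <- 0L
  for (it in seq_len(max_iter)) {
    moves <- propose()
    if (!length(moves)) break
    keys <- vapply(moves, function(m) move_key(m$op, m$a, m$b), character(1))
    deltas <- vapply(moves, `[[`, numeric(1), "delta")
    admissible <- !(keys %in% tabu)
    # a tabu move is admissible if it beats the best score seen (aspiration)
    admissible <- admissible | (total + deltas > best_score + 1e-12)
    if (!any(admissible)) break
    cand <- which(admissible)
    ord <- cand[order(-deltas[cand], keys[cand])]
    mv <- moves[[ord[1]]]

    if (mv$op == "add") {
      parents[[mv$b]] <- sort(c(parents[[mv$b]], mv$a))
      fs[[mv$b]] <- fam(mv$b, parents[[mv$b]])
      undo <- move_key("del", mv$a, mv$b)
    } else if (mv$op == "del") {
      parents[[mv$b]] <- setdiff(parents[[mv$b]], mv$a)
      fs[[mv$b]] <- fam(mv$b, parents[[mv$b]])
      undo <- move_key("add", mv$a, mv$b)
    } else {
      parents[[mv$b]] <- setdiff(parents[[mv$b]], mv$a)
      parents[[mv$a]] <- sort(c(parents[[mv$a]], mv$b))
      fs[[mv$b]] <- fam(mv$b, parents[[mv$b]])
      fs[[mv$a]] <- fam(mv$a, parents[[mv$a]])
      undo <- move_key("rev", mv$b, mv$a)
    }
    total <- sum(fs)
    tabu <- utils::tail(c(tabu, undo), tabu_len)
    if (total > best_score + 1e-12) {
      best_score <- total; best_parents <- parents
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
      if (no_improve >= patience) break
    }
  }
  bfs <- stats::setNames(vapply(nodes, function(j) fam(j, best_parents[[j]]),
                                numeric(1)), nodes)
  new_dag(nodes, best_parents, score = sum(bfs), family_scores = bfs)
}

#' Globally optimal DAG by exhaustive enumeration
#'
#' Enumerates every DAG on at most 4 variables, scores each by decomposable
#' BIC, and returns the global optimum (ties resolved to the
#' lexicographically least sorted edge list, so the empty graph wins exact
#' ties). Serves as the oracle for [tabu_search()].
#'
#' @param data discrete data.frame of factors with <= 4 columns.
#' @return the optimal `ev_dag`.
#' @export
exhaustive_search <- function(data) {
  d <- as_discrete_int(data)
  nodes <- colnames(d$m)
  p <- length(nodes)
  if (p > 4L) stop("exhaustive search supports at most 4 variables")
  idx <- stats::setNames(seq_len(p), nodes)
  # all family scores: node x parent subset
  subsets <- function(v) {
    if (!length(v)) return(list(character(0)))
    unlist(lapply(0:length(v), function(k)
      utils::combn(v, k, simplify = FALSE)), recursive = FALSE)
  }
  pkey <- function(s) paste0("(", paste(sort(s), collapse = ","), ")")
  fam_score <- lapply(nodes, function(j) {
    ss <- subsets(setdiff(nodes, j))
    stats::setNames(vapply(ss, function(s)
      bic_family_score_int(idx[[j]], idx[s], d), numeric(1)),
      vapply(ss, pkey, character(1)))
  })
  names(fam_score) <- nodes

  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[order(pairs$from, pairs$to), ]
  ne <- nrow(pairs)
  best <- NULL; best_score <- -Inf; best_key <- NULL
  for (mask in 0:(2^ne - 1)) {
    on <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(ne) - 1L)) != 0L)
    parents <- stats::setNames(rep(list(character(0)), p), nodes)
    for (k in on)
      parents[[pairs$to[k]]] <- c(parents[[pairs$to[k]]], pairs$from[k])
    # acyclicity by repeated leaf removal
    rem <- nodes; acyclic <- TRUE
    repeat {
      act <- parents[rem]
      roots <- rem[vapply(act, function(pp) !any(pp %in% rem), logical(1))]
      if (!length(roots)) { acyclic <- length(rem) == 0L; break }
      rem <- setdiff(rem, roots)
      if (!length(rem)) break
    }
    if (!acyclic) next
    sc <- sum(vapply(nodes, function(j)
      fam_score[[j]][[pkey(parents[[j]])]], numeric(1)))
    key <- paste(sort(sprintf("%s->%s", pairs$from[on], pairs$to[on])),
                 collapse = ";")
    if (sc > best_score + 1e-12 ||
        (abs(sc - best_score) <= 1e-12 && !is.null(best_key) &&
         key < best_key)) {
      best_score <- sc; best_key <- key
      best <- lapply(parents, sort)
    }
  }
  fs <- stats::setNames(vapply(nodes, function(j)
    fam_score[[j]][[pkey(best[[j]])]], numeric(1)), nodes)
  new_dag(nodes, best, score = best_score, family_scores = fs)
}

#' Causes and consequences of a node
#'
#' Causes are the node's parents in the learned DAG, consequences its
#' children; the induced subnetwork covers the node with its parents and
#' children.
#'
#' @param dag an `ev_dag`.
#' @param node node name.
#' @return list: `causes`, `consequences`, `subnetwork` (edge data.frame
#'   among the node, its parents and its children).
#' @export
neighborhood <- function(dag, node) {
  if (!node %in% dag$nodes) stop("unknown node: ", node)
  causes <- dag$parents[[node]]
  e <- dag_edges(dag)
  consequences <- sort(e$to[e$from == node])
  keep <- c(node, causes, consequences)
  sub <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  list(causes = sort(causes), consequences = consequences,
       subnetwork = sub)
}

#' Sample observations from a binary Bayesian network
#'
#' Forward-samples binary variables (levels low/high or false/true) in
#' topological order. Used to generate ground-truth datasets for
#' structure-recovery tests.
#'
#' @param parents named list: parent names per node (must be acyclic).
#' @param prob_high named list: for each node, a numeric vector of
#'   P(second level) per parent configuration (parents vary fastest in the
#'   order listed; length `2^n_parents`).
#' @param n number of observations.
#' @param seed integer seed.
#' @param levels level names (default c("low", "high")).
#' @return data.frame of factors.
#' @export
sim_discrete_bn <- function(parents, prob_high, n, seed = 1L,
                            levels = c("low", "high")) {
  set.seed(seed)
  nodes <- names(parents)
  out <- matrix(NA_integer_, n, length(nodes),
                dimnames = list(NULL, nodes))
  done <- character(0)
  while (length(done) < length(nodes)) {
    ready <- setdiff(nodes[vapply(parents, function(p)
      all(p %in% done), logical(1))], done)
    if (!length(ready)) stop("parent structure is cyclic")
    for (j in ready) {
      pa <- parents[[j]]
      if (!length(pa)) {
        pr <- rep(prob_high[[j]][1], n)
      } else {
        cfg <- rep(1L, n); mult <- 1L
        for (k in pa) {
          cfg <- cfg + (out[, k] - 1L) * mult
          mult <- mult * 2L
        }
        pr <- prob_high[[j]][cfg]
      }
      out[, j] <- 1L + stats::rbinom(n, 1L, pr)
    }
    done <- c(done, ready)
  }
  as.data.frame(lapply(stats::setNames(nodes, nodes), function(j)
    factor(levels[out[, j]], levels = levels)), optional = TRUE)
}
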