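#' Build a CSR structure from an edge list
#'
#' Compressed sparse row storage with one row per postsynaptic cell:
#' \code{p} is the row pointer (length \code{n_post + 1}), \code{j} the
#' presynaptic column indices, both 0-based. Duplicate (pre, post) pairs
#' are collapsed; within each row indices are sorted ascending.
#'
#' @param pre,post Integer vectors of 0-based pre/post ids (equal length).
#' @param n_pre,n_post Population sizes.
#' @return List with elements \code{p}, \code{j}, \code{n_pre},
#'   \code{n_post}; \code{p[n_post + 1]} equals the synapse count.
#' @export
#' @examples
#' csr_from_edges(c(0, 1, 0), c(0, 0, 1), 2, 2)$p  # 0 2 3
csr_from_edges <- function(pre, post, n_pre, n_post) {
  stopifnot(length(pre) == length(post))
  pre <- as.integer(pre); post <- as.integer(post)
  if (length(pre) && (min(pre) < 0L || max(pre) >= n_pre)) {
    stop("presynaptic index out of range", call. = FALSE)
  }
  if (length(post) && (min(post) < 0L || max(post) >= n_post)) {
    stop("postsynaptic index out of range", call. = FALSE)
  }
  o <- order(post, pre)
  pre <- pre[o]; post <- post[o]
  if (length(pre) > 1L) {
    dup <- c(FALSE, pre[-1L] == pre[-length(pre)] & post[-1L] == post[-length(post)])
    pre <- pre[!dup]; post <- post[!dup]
  }
  p <- c(0L, cumsum(tabulate(post + 1L, nbins = n_post)))
  list(p = as.integer(p), j = pre, n_pre = as.integer(n_pre),
       n_post = as.integer(n_post))
}

#' Expand a CSR structure back to an edge tibble
#' @param csr A CSR list as returned by [csr_from_edges()].
#' @return Tibble with 0-based columns \code{pre}, \code{post}.
#' @export
expand_csr <- function(csr) {
  counts <- diff(csr$p)
  tibble::tibble(
    pre = csr$j,
    post = rep(seq_len(csr$n_post) - 1L, counts)
  )
}

# draw edges for one rule; returns list(pre, post) of 0-based local ids
draw_rule_edges <- function(rule, pre_tab, post_tab, relax_indegree = FALSE) {
  n_pre <- nrow(pre_tab); n_post <- nrow(post_tab)
  if (n_pre == 0L || n_post == 0L) return(list(pre = integer(), post = integer()))
  same_type <- identical(rule$pre, rule$post)

  if (rule$geometry == "all_to_all") {
    pre <- rep(seq_len(n_pre) - 1L, times = n_post)
    post <- rep(seq_len(n_post) - 1L, each = n_pre)
    if (same_type) {
      keep <- pre != post
      pre <- pre[keep]; post <- post[keep]
    }
    return(list(pre = pre, post = post))
  }

  k <- rule$k
  planar <- rule$geometry %in% c("fixed_indegree", "cylinder")
  sagittal <- rule$geometry %in% c("sagittal_band", "band_indegree", "sagittal_fixed")
  r <- rule$radius  # planar radius or sagittal halfwidth, um
  take_all <- rule$geometry %in% c("sagittal_band") ||
    (rule$geometry == "cylinder" && (is.na(k) || !is.finite(k)))

  pre_list <- vector("list", n_post)
  # chunk posts so the distance matrix stays ~2e6 entries
  chunk <- max(1L, as.integer(2e6 / max(1L, n_pre)))
  starts <- seq(1L, n_post, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, n_post)
    if (planar && is.finite(r)) {
      d2 <- outer(post_tab$x[idx], pre_tab$x, `-`)^2 +
        outer(post_tab$y[idx], pre_tab$y, `-`)^2
      inr <- d2 <= r^2
    } else if (sagittal && is.finite(r)) {
      inr <- abs(outer(post_tab$y[idx], pre_tab$y, `-`)) <= r
    } else {
      inr <- matrix(TRUE, length(idx), n_pre)
    }
    for (m in seq_along(idx)) {
      i <- idx[m]
      cand <- which(inr[m, ])
      if (same_type) cand <- cand[cand != i]
      if (take_all) {
        pre_list[[i]] <- cand - 1L
      } else {
        if (length(cand) < k) {
          if (!relax_indegree) {
            stop(sprintf(
              "rule %s: fixed in-degree %d exceeds the %d presynaptic cells in range of postsynaptic cell %d",
              rule$name, k, length(cand), i - 1L), call. = FALSE)
          }
          pre_list[[i]] <- cand - 1L
        } else {
          pre_list[[i]] <- sort(cand[sample.int(length(cand), k)]) - 1L
        }
      }
    }
  }
  counts <- lengths(pre_list)
  list(pre = unlist(pre_list, use.names = FALSE) %||% integer(),
       post = rep(seq_len(n_post) - 1L, counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the structural connectome
#'
#' Realizes every connection rule against a placement and stores each
#' projection as a CSR matrix (rows = postsynaptic cells) together with the
#' rule's scalar weight (nS) and delay (ms).
#'
#' @param p A placement from [place_populations()].
#' @param rules Tibble of rules, default [connection_rules()].
#' @param seed Integer seed; the build is deterministic given the seed.
#' @param relax_indegree If TRUE, a fixed in-degree larger than the number
#'   of in-range presynaptic cells is truncated (with one warning per rule)
#'   instead of raising an error. Used for miniature fixtures.
#' @return A \code{synapse_store}: named list of rule realizations, each
#'   holding the rule row and a \code{csr}.
#' @export
build_connectivity <- function(p, rules = connection_rules(), seed = 1,
                               relax_indegree = FALSE) {
  set.seed(as.integer(seed))
  tabs <- lapply(stats::setNames(nm = unique(c(rules$pre, rules$post))),
                 function(tp) p[p$cell_type == tp, c("x", "y", "z")])
  store <- vector("list", nrow(rules))
  names(store) <- rules$name
  for (i in seq_len(nrow(rules))) {
    rule <- as.list(rules[i, ])
    pre_tab <- tabs[[rule$pre]]; post_tab <- tabs[[rule$post]]
    edges <- draw_rule_edges(rule, pre_tab, post_tab, relax_indegree)
    if (relax_indegree && !is.na(rule$k) && nrow(post_tab) > 0 &&
        rule$geometry %in% c("fixed_indegree", "cylinder", "band_indegree",
                             "sagittal_fixed") &&
        length(edges$pre) < rule$k * nrow(post_tab)) {
      warning(sprintf("rule %s: in-degree truncated to available presynaptic cells",
                      rule$name), call. = FALSE)
    }
    store[[i]] <- list(
      name = rule$name, pre = rule$pre, post = rule$post, sign = rule$sign,
      weight = rule$weight, delay = as.integer(rule$delay),
      csr = csr_from_edges(edges$pre, edges$post,
                           nrow(pre_tab), nrow(post_tab))
    )
  }
  structure(store, class = "synapse_store")
}

#' @export
print.synapse_store <- function(x, ...) {
  cat("<synapse_store>", length(x), "connection rules\n")
  for (r in x) {
    cat(sprintf("  %-8s %s -> %s (%s) w=%g nS d=%d ms, %d synapses\n",
                r$name, r$pre, r$post, r$sign, r$weight, r$delay,
                r$csr$p[length(r$csr$p)]))
  }
  invisible(x)
}

#' Per-rule degree summary
#'
#' @param store A synapse store.
#' @return Tibble with per-rule synapse counts and in/out-degree statistics.
#' @export
degree_summary <- function(store) {
  purrr::map_dfr(store, function(r) {
    indeg <- diff(r$csr$p)
    outdeg <- tabulate(r$csr$j + 1L, nbins = r$csr$n_pre)
    tibble::tibble(
      name = r$name, pre = r$pre, post = r$post,
      n_synapses = sum(indeg),
      in_mean = if (length(indeg)) mean(indeg) else 0,
      in_sd = if (length(indeg) > 1) stats::sd(indeg) else 0,
      in_min = if (length(indeg)) min(indeg) else 0,
      in_max = if (length(indeg)) max(indeg) else 0,
      out_mean = if (length(outdeg)) mean(outdeg) else 0,
      out_sd = if (length(outdeg) > 1) stats::sd(outdeg) else 0
    )
  })
}

#' Serialize / load a synapse store as plain text
#'
#' Writes a rules manifest (\code{manifest.csv}) plus one whitespace edge
#' list per rule (\code{edges_<name>.tsv}, 0-based \code{pre post} local
#' ids), the interchange format for externally generated connectomes.
#'
#' @param store A synapse store.
#' @param dir Directory (created if needed).
#' @return \code{write_store} returns \code{dir} invisibly;
#'   \code{read_store} returns a synapse store.
#' @export
write_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- purrr::map_dfr(store, function(r) {
    tibble::tibble(name = r$name, pre = r$pre, post = r$post, sign = r$sign,
                   weight = r$weight, delay = r$delay,
                   n_pre = r$csr$n_pre, n_post = r$csr$n_post)
  })
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  for (r in store) {
    e <- expand_csr(r$csr)
    utils::write.table(e, file.path(dir, paste0("edges_", r$name, ".tsv")),
                       row.names = FALSE, col.names = TRUE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_store
#' @export
read_store <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  store <- vector("list", nrow(man))
  names(store) <- man$name
  for (i in seq_len(nrow(man))) {
    e <- utils::read.table(file.path(dir, paste0("edges_", man$name[i], ".tsv")),
                           header = TRUE)
    store[[i]] <- list(
      name = man$name[i], pre = man$pre[i], post = man$post[i],
      sign = man$sign[i], weight = man$weight[i],
      delay = as.integer(man$delay[i]),
      csr = csr_from_edges(e$pre, e$post, man$n_pre[i], man$n_post[i])
    )
  }
  structure(store, class = "synapse_store")
}
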