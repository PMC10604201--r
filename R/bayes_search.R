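# Hyperparameter search over the admissible integer boxes of the seven
# Dilated ResNet hyperparameters. Two seeded backends: plain random
# search, and a sequential model-based backend that alternates between a
# nearest-neighbour surrogate over the points evaluated so far and local
# moves around the incumbent.

#' Search the Dilated ResNet hyperparameter box
#'
#' Minimizes `objective(config)` (typically a validation MAE) over the
#' integer ranges of [dilated_resnet_config()]. A configuration whose
#' objective evaluation fails is scored `+Inf` with a warning and the
#' search continues.
#'
#' @param objective Function taking a [dilated_resnet_config()] and
#'   returning a scalar score to minimize.
#' @param budget Number of objective evaluations (>= 1).
#' @param seed Search seed.
#' @param backend `"smbo"` (sequential model-based, default) or
#'   `"random"`.
#' @param input_len,input_channels Fixed input geometry for the proposed
#'   configurations.
#' @param n_candidates Candidate pool size per SMBO iteration.
#' @return The best configuration found, with attribute `evaluations`
#'   (data.frame of all scored proposals).
#' @export
bayes_search <- function(objective, budget, seed = 1L,
                         backend = c("smbo", "random"),
                         input_len = 1800L, input_channels = 1L,
                         n_candidates = 50L) {
  backend <- match.arg(backend)
  if (budget < 1L) stop("budget must be >= 1", call. = FALSE)
  box <- .drn_search_box()
  dims <- names(box)
  span <- vapply(box, function(b) b[2] - b[1] + 1, numeric(1))

  draw <- function() vapply(dims, function(d)
    sample(box[[d]][1]:box[[d]][2], 1L), integer(1))
  neighbors <- function(p) {
    out <- list()
    for (d in dims) for (dl in c(-1L, 1L)) {
      q <- p
      q[d] <- q[d] + dl
      if (q[d] >= box[[d]][1] && q[d] <= box[[d]][2]) out <- c(out, list(q))
    }
    out
  }
  as_cfg <- function(p) do.call(dilated_resnet_config,
                                c(as.list(p), list(input_len = input_len,
                                                   input_channels = input_channels)))
  score <- function(p) {
    tryCatch(objective(as_cfg(p)), error = function(e) {
      warning(sprintf("objective failed for (%s): %s",
                      paste(p, collapse = ","), conditionMessage(e)),
              call. = FALSE)
      Inf
    })
  }

  .with_seed(seed, {
    evals <- list()
    seen <- character(0)
    push <- function(p) {
      key <- paste(p, collapse = ",")
      if (key %in% seen) return(FALSE)
      s <- score(p)
      evals[[length(evals) + 1L]] <<- c(p, score = s)
      seen <<- c(seen, key)
      TRUE
    }
    if (backend == "random") {
      while (length(evals) < budget) push(draw())
    } else {
      n0 <- min(budget, max(4L, budget %/% 5L))
      while (length(evals) < n0) push(draw())
      while (length(evals) < budget) {
        tab <- do.call(rbind, evals)
        best_idx <- which.min(tab[, "score"])
        incumbent <- tab[best_idx, dims]
        cand <- c(neighbors(incumbent),
                  replicate(n_candidates, draw(), simplify = FALSE))
        cand <- cand[!vapply(cand, function(p)
          paste(p, collapse = ",") %in% seen, logical(1))]
        if (length(cand) == 0L) {
          if (!push(draw())) break
          next
        }
        # nearest-neighbour surrogate on range-normalized coordinates
        fin <- is.finite(tab[, "score"])
        if (!any(fin)) {
          push(draw())
          next
        }
        Xf <- sweep(tab[fin, dims, drop = FALSE], 2L, span, "/")
        sf <- tab[fin, "score"]
        surrogate <- vapply(cand, function(p) {
          d2 <- colSums((t(Xf) - p / span)^2)
          w <- 1 / (d2 + 1e-6)
          sum(w * sf) / sum(w)
        }, numeric(1))
        push(cand[[which.min(surrogate)]])
      }
    }
    tab <- as.data.frame(do.call(rbind, evals))
    best <- tab[which.min(tab$score), dims]
    structure(as_cfg(unlist(best)), evaluations = tab)
  })
}
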