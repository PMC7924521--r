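#' One-hot interval expansion (LP encoding)
#'
#' Expands each observation into binary interval indicators: every main
#' effect contributes a block holding a single 1 at the interval the
#' value falls in (intervals are lower-closed, upper-open, with the
#' extremes open to -Inf/+Inf); every two-way interaction contributes the
#' column-major vectorisation of the joint interval-grid indicator, again
#' a single 1. Blocks are concatenated in group order.
#'
#' An unseen categorical level at transform time yields an all-zero block
#' with a warning (the observation contributes no points for that
#' effect).
#'
#' @param x data frame with the training schema.
#' @param scheme an [build_scheme()] result.
#' @param groups effects to encode; defaults to `scheme$groups`.
#' @return A list of class `ics_expanded`: binary matrix `z`
#'   (`N x N_s`), `column_map` data frame (`effect`, `k`, `l`), `groups`,
#'   and `encoding = "lp"`.
#' @export
lp_encode <- function(x, scheme, groups = scheme$groups) {
  n <- nrow(x)
  blocks <- vector("list", length(groups))
  maps <- vector("list", length(groups))
  warned <- FALSE
  for (e in seq_along(groups)) {
    g <- groups[[e]]
    if (length(g) == 1) {
      var <- scheme$vars[[g]]
      idx <- interval_index(x[[g]], var)
      if (anyNA(idx)) warned <- TRUE
      np <- var$n_intervals
      z <- matrix(0, n, np)
      ok <- !is.na(idx)
      z[cbind(which(ok), idx[ok])] <- 1
      blocks[[e]] <- z
      maps[[e]] <- data.frame(effect = e, k = seq_len(np), l = NA_integer_)
    } else {
      v1 <- scheme$vars[[g[1]]]; v2 <- scheme$vars[[g[2]]]
      i1 <- interval_index(x[[g[1]]], v1)
      i2 <- interval_index(x[[g[2]]], v2)
      if (anyNA(i1) || anyNA(i2)) warned <- TRUE
      n1 <- v1$n_intervals; n2 <- v2$n_intervals
      z <- matrix(0, n, n1 * n2)
      ok <- !is.na(i1) & !is.na(i2)
      ## column-major vectorisation of the n1 x n2 grid: cell (k, l) -> (l-1)*n1 + k
      z[cbind(which(ok), (i2[ok] - 1L) * n1 + i1[ok])] <- 1
      blocks[[e]] <- z
      maps[[e]] <- data.frame(effect = e,
                              k = rep(seq_len(n1), times = n2),
                              l = rep(seq_len(n2), each = n1))
    }
  }
  if (warned)
    warning("unseen level(s) at transform time: all-zero block(s) emitted",
            call. = FALSE)
  structure(list(z = do.call(cbind, blocks),
                 column_map = do.call(rbind, maps),
                 groups = groups, encoding = "lp"),
            class = "ics_expanded")
}

#' Cumulative interval expansion (elastic-net encoding)
#'
#' Expands each observation so that its interval and all preceding
#' intervals of the same variable are 1: per variable the block is
#' `[1, I(x >= tau_1), ..., I(x >= tau_{Np-1})]`. Coefficients fitted on
#' this encoding live in the difference domain: each one is the change
#' with respect to the previous interval. Main effects only. Categorical
#' variables use their catalogued level order.
#'
#' @inheritParams lp_encode
#' @return An `ics_expanded` list with `encoding = "en"`.
#' @export
en_encode <- function(x, scheme, groups = scheme$groups) {
  if (any(lengths(groups) == 2))
    stop("the cumulative encoding supports main effects only", call. = FALSE)
  n <- nrow(x)
  blocks <- vector("list", length(groups))
  maps <- vector("list", length(groups))
  warned <- FALSE
  for (e in seq_along(groups)) {
    g <- groups[[e]]
    var <- scheme$vars[[g]]
    idx <- interval_index(x[[g]], var)
    if (anyNA(idx)) warned <- TRUE
    np <- var$n_intervals
    ## column j is I(interval index >= j); column 1 is all ones
    z <- outer(idx, seq_len(np), ">=") * 1
    z[is.na(z)] <- 0
    blocks[[e]] <- z
    maps[[e]] <- data.frame(effect = e, k = seq_len(np), l = NA_integer_)
  }
  if (warned)
    warning("unseen level(s) at transform time: all-zero block(s) emitted",
            call. = FALSE)
  structure(list(z = do.call(cbind, blocks),
                 column_map = do.call(rbind, maps),
                 groups = groups, encoding = "en"),
            class = "ics_expanded")
}

#' Adjacent-interval difference and reconstruction matrices
#'
#' The difference matrix `D` has one row per adjacent interval pair
#' within an effect: a continuous/ordinal/binary main effect with `Np`
#' intervals contributes `Np - 1` first-difference rows; a categorical
#' effect contributes one row per non-reference level against the first
#' catalogued level (levels have no natural adjacency); a `k x l`
#' interaction grid contributes `k(l-1)` horizontal plus `l(k-1)`
#' vertical rows. The L1 norm of `D w` is the total-variation penalty of
#' the LP formulation.
#'
#' For main-effect schemes the structure also carries the square
#' per-variable operator `d_full` (first row selects the first interval
#' weight, subsequent rows are adjacent differences) and its inverse
#' `r`, the block lower-triangular-of-ones reconstruction matrix mapping
#' difference-domain weights back to interval weights.
#'
#' @inheritParams lp_encode
#' @return A list of class `ics_diffstruct`: sparse `d` (`N_ds x N_s`),
#'   `row_map` (effect per row), and for main-effects-only groups the
#'   sparse `r` and `d_full`.
#' @export
build_difference_structure <- function(scheme, groups = scheme$groups) {
  offs <- c(0, cumsum(vapply(groups, function(g) effect_size(scheme, g), 0)))
  ns <- offs[length(offs)]
  ip <- c(); im <- c(); row_map <- c()
  r <- 0L
  for (e in seq_along(groups)) {
    g <- groups[[e]]
    o <- offs[e]
    if (length(g) == 1) {
      var <- scheme$vars[[g]]
      np <- var$n_intervals
      if (np >= 2) {
        if (var$var_type == "categorical") {
          ## star to the reference (first catalogued) level
          ip <- c(ip, o + 2:np); im <- c(im, rep(o + 1L, np - 1L))
        } else {
          ip <- c(ip, o + 2:np); im <- c(im, o + 1:(np - 1L))
        }
        row_map <- c(row_map, rep(e, np - 1L))
        r <- r + np - 1L
      }
    } else {
      n1 <- scheme$vars[[g[1]]]$n_intervals
      n2 <- scheme$vars[[g[2]]]$n_intervals
      cell <- function(k, l) o + (l - 1L) * n1 + k
      ## horizontal: (k, l+1) - (k, l); vertical: (k+1, l) - (k, l)
      for (l in seq_len(n2 - 1L)) for (k in seq_len(n1)) {
        ip <- c(ip, cell(k, l + 1L)); im <- c(im, cell(k, l)); row_map <- c(row_map, e)
      }
      for (l in seq_len(n2)) for (k in seq_len(n1 - 1L)) {
        ip <- c(ip, cell(k + 1L, l)); im <- c(im, cell(k, l)); row_map <- c(row_map, e)
      }
      r <- r + n1 * (n2 - 1L) + n2 * (n1 - 1L)
    }
  }
  nds <- length(ip)
  d <- Matrix::sparseMatrix(i = c(seq_len(nds), seq_len(nds)),
                            j = c(ip, im), x = c(rep(1, nds), rep(-1, nds)),
                            dims = c(nds, ns))
  out <- list(d = d, row_map = row_map, n_ds = nds, n_s = ns)

  if (all(lengths(groups) == 1)) {
    rb <- vector("list", length(groups)); db <- vector("list", length(groups))
    for (e in seq_along(groups)) {
      np <- scheme$vars[[groups[[e]]]]$n_intervals
      lower <- Matrix::tril(Matrix::Matrix(1, np, np, sparse = TRUE))
      rb[[e]] <- lower
      db[[e]] <- Matrix::solve(lower)  # first row e1, then first differences
    }
    out$r <- Matrix::bdiag(rb)
    out$d_full <- Matrix::bdiag(db)
  }
  structure(out, class = "ics_diffstruct")
}
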