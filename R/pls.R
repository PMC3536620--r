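# Mean-centered task PLS and seed PLS. Task PLS decomposes the grand-mean
# centered condition x region mean matrix by SVD; each latent variable (LV)
# pairs a design salience (condition contrast) with a region salience
# pattern and a singular value. Seed PLS decomposes stacked seed-to-region
# correlation maps, one row per condition x seed. Inference: permutation
# of subject-to-condition assignment for LV significance, within-condition
# bootstrap for salience standard errors and bootstrap ratios (BSR), with
# |BSR| >= 3 the conventional reliability cutoff.

.check_tables <- function(tables, min_subjects = 2L) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  regs <- tables[[1L]]$regions
  for (tb in tables) {
    stopifnot(inherits(tb, "activity_table"))
    if (!identical(tb$regions, regs))
      stop("all condition tables must share an identical region order")
    if (length(tb$subjects) < min_subjects)
      stop(sprintf("condition '%s' has %d subjects; need >= %d",
                   tb$group_label, length(tb$subjects), min_subjects))
  }
  regs
}

.condition_labels <- function(tables) {
  labs <- vapply(tables, function(t) t$group_label, character(1))
  if (anyDuplicated(labs)) labs <- make.unique(labs)
  labs
}

# SVD of the grand-mean centered condition-mean matrix built from a pooled
# regions x subjects matrix plus a condition factor.
.task_svd <- function(pooled, cond) {
  m <- t(vapply(levels(cond), function(l) {
    rowMeans(pooled[, cond == l, drop = FALSE])
  }, numeric(nrow(pooled))))
  mc <- sweep(m, 2L, colMeans(m))
  svd(mc)
}

# Stacked seed-to-region correlation maps ((condition x seed) x regions).
.seed_maps <- function(pooled, cond, seed_idx, regs, strict = TRUE) {
  rows <- list()
  for (l in levels(cond)) {
    x <- pooled[, cond == l, drop = FALSE]
    for (s in seed_idx) {
      if (sd(x[s, ]) == 0) {
        if (strict)
          stop(sprintf("seed '%s' has zero variance in condition '%s'",
                       regs[s], l))
        rows[[length(rows) + 1L]] <- rep(0, nrow(x))
        next
      }
      rr <- suppressWarnings(
        as.numeric(cor(x[s, ], t(x))))
      rr[is.na(rr)] <- 0   # zero-variance target region
      rows[[length(rows) + 1L]] <- rr
    }
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- as.vector(t(outer(levels(cond), regs[seed_idx],
                                     paste, sep = ":")))
  colnames(mat) <- regs
  mat
}

.pls_result <- function(sv, type, conditions, regions, row_labels) {
  k <- length(sv$d)
  structure(
    list(type = type,
         singular_values = sv$d,
         design_saliences = structure(sv$u,
           dimnames = list(row_labels, paste0("LV", seq_len(k)))),
         region_saliences = structure(sv$v,
           dimnames = list(regions, paste0("LV", seq_len(k)))),
         conditions = conditions,
         regions = regions),
    class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("%s PLS: %d conditions, %d regions\n",
              x$type, length(x$conditions), length(x$regions)))
  cat("singular values:",
      paste(format(x$singular_values, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Mean-centered task PLS
#'
#' Builds the condition x region matrix of condition means, centers every
#' column by its grand mean across conditions, and decomposes it by SVD.
#' LV k pairs the design salience (column k of `design_saliences`, the
#' condition contrast) with the region salience pattern (column k of
#' `region_saliences`) at singular value `singular_values[k]`.
#'
#' @param tables List of [activity_table()], one per condition, sharing a
#'   region order; each needs >= 2 subjects.
#' @return A `pls_result`.
#' @export
#' @examples
#' # two conditions differing only on the third region
#' t1 <- activity_table(matrix(10, 3, 4,
#'        dimnames = list(c("a", "b", "c"), NULL)), "ctrl")
#' v <- matrix(10, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
#' v[3, ] <- 20
#' t2 <- activity_table(v, "trained")
#' task_pls(list(t1, t2))$singular_values[1]  # 5 * sqrt(2)
task_pls <- function(tables) {
  if (length(tables) < 2L) stop("task PLS needs >= 2 conditions")
  regs <- .check_tables(tables, min_subjects = 2L)
  labs <- .condition_labels(tables)
  pooled <- do.call(cbind, lapply(tables, `[[`, "values"))
  cond <- factor(rep(labs, vapply(tables, function(t)
    length(t$subjects), integer(1))), levels = labs)
  .pls_result(.task_svd(pooled, cond), "task", labs, regs, labs)
}

#' Seed PLS of condition-wise seed correlation maps
#'
#' For every condition and every seed region, the correlation vector
#' between the seed's activity and all regions (across that condition's
#' subjects) forms one row; the stacked matrix is decomposed by SVD
#' without centering. Design saliences contrast the (condition x seed)
#' rows, region saliences weight the regions.
#'
#' @param tables List of [activity_table()], one per condition, each with
#'   >= 4 subjects.
#' @param seeds Nonempty character vector of seed regions.
#' @return A `pls_result` (row labels `condition:seed`).
#' @export
seed_pls <- function(tables, seeds) {
  if (length(seeds) == 0L) stop("'seeds' must be nonempty")
  regs <- .check_tables(tables, min_subjects = 4L)
  labs <- .condition_labels(tables)
  seed_idx <- .region_idx(regs, seeds)
  pooled <- do.call(cbind, lapply(tables, `[[`, "values"))
  cond <- factor(rep(labs, vapply(tables, function(t)
    length(t$subjects), integer(1))), levels = labs)
  maps <- .seed_maps(pooled, cond, seed_idx, regs)
  .pls_result(svd(maps), "seed", labs, regs, rownames(maps))
}

#' Permutation test of PLS latent variables
#'
#' Shuffles the subject-to-condition assignment (resampling without
#' replacement at the original condition sizes), recomputes the PLS
#' singular values, and reports for each LV
#' `p = (#[permuted s_k >= observed s_k] + 1) / (n_perm + 1)`.
#'
#' @param tables List of [activity_table()], one per condition.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional RNG seed.
#' @param seeds When given, the test is run for [seed_pls()] with these
#'   seed regions; otherwise for [task_pls()].
#' @return Numeric vector of per-LV permutation p-values.
#' @export
permutation_test_lvs <- function(tables, n_perm = 500, seed = NULL,
                                 seeds = NULL) {
  if (!is_count(n_perm, 100L)) stop("'n_perm' must be a count >= 100")
  regs <- .check_tables(tables, if (is.null(seeds)) 2L else 4L)
  labs <- .condition_labels(tables)
  pooled <- do.call(cbind, lapply(tables, `[[`, "values"))
  cond <- factor(rep(labs, vapply(tables, function(t)
    length(t$subjects), integer(1))), levels = labs)
  sv_of <- if (is.null(seeds)) {
    function(cnd) .task_svd(pooled, cnd)$d
  } else {
    seed_idx <- .region_idx(regs, seeds)
    function(cnd) svd(.seed_maps(pooled, cnd, seed_idx, regs,
                                 strict = FALSE))$d
  }
  obs <- sv_of(cond)
  count <- integer(length(obs))
  with_rng(seed, {
    for (p in seq_len(n_perm)) {
      perm <- factor(sample(as.character(cond)), levels = labs)
      count <- count + (sv_of(perm) >= obs)
    }
  })
  (count + 1) / (n_perm + 1)
}

#' Bootstrap salience ratios (BSR)
#'
#' Resamples subjects with replacement *within* each condition, recomputes
#' the PLS, aligns every replicate LV's sign to the original (flipping when
#' the dot product of region saliences is negative), and divides the
#' original salience by the bootstrap standard error. Regions with
#' `|BSR| >= 3` are flagged reliable. A zero bootstrap SE yields an
#' infinite BSR with a warning.
#'
#' @param tables List of [activity_table()], one per condition.
#' @param n_boot Bootstrap replicates (>= 100).
#' @param seed Optional RNG seed.
#' @param seeds When given, bootstrap for [seed_pls()] instead of
#'   [task_pls()].
#' @param bsr_cutoff Reliability cutoff on |BSR| (default 3, roughly a 0.01
#'   confidence level).
#' @return List with `bsr` (regions x LV), `se`, `reliable` (logical
#'   matrix), `saliences` (original), `n_boot`.
#' @export
bootstrap_salience_ratios <- function(tables, n_boot = 500, seed = NULL,
                                      seeds = NULL, bsr_cutoff = 3) {
  if (!is_count(n_boot, 100L)) stop("'n_boot' must be a count >= 100")
  regs <- .check_tables(tables, if (is.null(seeds)) 2L else 4L)
  labs <- .condition_labels(tables)
  sizes <- vapply(tables, function(t) length(t$subjects), integer(1))
  pooled <- do.call(cbind, lapply(tables, `[[`, "values"))
  cond <- factor(rep(labs, sizes), levels = labs)
  v_of <- if (is.null(seeds)) {
    function(x) .task_svd(x, cond)$v
  } else {
    seed_idx <- .region_idx(regs, seeds)
    function(x) svd(.seed_maps(x, cond, seed_idx, regs,
                               strict = FALSE))$v
  }
  v0 <- v_of(pooled)
  k <- ncol(v0)
  offsets <- c(0L, cumsum(sizes))
  acc <- array(0, dim = c(nrow(v0), k, n_boot))
  with_rng(seed, {
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(seq_along(sizes), function(ci) {
        offsets[ci] + sample.int(sizes[ci], sizes[ci], replace = TRUE)
      }))
      vb <- v_of(pooled[, idx, drop = FALSE])
      flip <- sign(colSums(vb * v0))
      flip[flip == 0] <- 1
      acc[, , b] <- sweep(vb, 2L, flip, `*`)
    }
  })
  se <- apply(acc, c(1L, 2L), sd)
  if (any(se == 0))
    warning("zero bootstrap SE for some saliences; BSR reported infinite")
  bsr <- v0 / se
  dimnames(bsr) <- dimnames(se) <- list(regs, paste0("LV", seq_len(k)))
  list(bsr = bsr, se = se, reliable = abs(bsr) >= bsr_cutoff,
       saliences = structure(v0, dimnames = dimnames(bsr)),
       n_boot = n_boot)
}
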