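#' Decompose fitted blocks into unit-norm rank-one components
#'
#' Each block pair `(WX, WY)` is rewritten as `WX_tilde %*% DX %*% DY %*%
#' WY_tilde` where the columns of `WX_tilde` and rows of `WY_tilde` have unit
#' Euclidean norm and `DX`, `DY` are diagonal with the removed norms. The
#' product of the two diagonal entries is the module's importance weight;
#' modules are returned sorted by decreasing importance. Signs are fixed so
#' each miRNA vector's largest-magnitude entry is positive (the mRNA vector
#' is flipped jointly, leaving the rank-one product unchanged).
#'
#' @param params An [mtfr_params()] object.
#' @param cohort_names Optional labels for the cohort scopes.
#' @return A list with one element per scope (`"tissue"`, then each cohort):
#'   `WX_tilde` (D x R), `WY_tilde` (R x T), `dx`, `dy` (length-R norm
#'   vectors), `importance` (sorted, decreasing), `scope`.
#' @export
decompose_params <- function(params, cohort_names = NULL) {
  K <- length(params$WXk)
  cohort_names <- cohort_names %||% paste0("cohort", seq_len(K))
  one <- function(WX, WY, scope) {
    dx <- sqrt(colSums(WX^2))
    dy <- sqrt(rowSums(WY^2))
    keep <- which(dx > 0 & dy > 0)
    if (length(keep) < length(dx)) {
      warning(sprintf("scope '%s': dropped %d zero-norm module(s)", scope,
                      length(dx) - length(keep)), call. = FALSE)
    }
    WX <- WX[, keep, drop = FALSE]
    WY <- WY[keep, , drop = FALSE]
    dx <- dx[keep]
    dy <- dy[keep]
    if (length(keep)) {
      WXt <- sweep(WX, 2L, dx, `/`)
      WYt <- sweep(WY, 1L, dy, `/`)
      for (r in seq_along(dx)) {
        s <- sign(WXt[which.max(abs(WXt[, r])), r])
        if (s < 0) {
          WXt[, r] <- -WXt[, r]
          WYt[r, ] <- -WYt[r, ]
        }
      }
      ord <- order(dx * dy, decreasing = TRUE)
      WXt <- WXt[, ord, drop = FALSE]
      WYt <- WYt[ord, , drop = FALSE]
      dx <- dx[ord]
      dy <- dy[ord]
    } else {
      WXt <- WX
      WYt <- WY
    }
    list(scope = scope, WX_tilde = WXt, WY_tilde = WYt, dx = dx, dy = dy,
         importance = dx * dy)
  }
  c(list(one(params$WXS, params$WYS, "tissue")),
    lapply(seq_len(K), function(k) one(params$WXk[[k]], params$WYk[[k]], cohort_names[k])))
}

#' Select the features a module loads on
#'
#' A feature is selected when the magnitude of its unit-norm weight exceeds
#' `2 / sqrt(length(weights))` (strictly), i.e. twice the root-mean-square
#' weight a uniformly spread module would give every feature.
#'
#' @param weights Named unit-norm numeric vector.
#' @return Character vector of selected feature ids.
#' @export
select_features <- function(weights) {
  thr <- 2 / sqrt(length(weights))
  names(weights)[abs(weights) > thr]
}

#' Extract ranked regulatory modules from a fit
#'
#' Converts each surviving rank-one component of the fitted factorization
#' into a regulatory module: a scope (tissue-shared or one cohort), a rank
#' index (1 = most important within its scope), an importance weight, the
#' unit-norm miRNA and mRNA weight vectors, and the selected feature sets
#' from the `2/sqrt(.)` rule.
#'
#' @param fit An `mtfr_fit` object (or an [mtfr_params()] with `mirna_ids`,
#'   `mrna_ids`, `cohort_names` supplied).
#' @param mirna_ids,mrna_ids,cohort_names Overrides for the identifier lists
#'   stored in the fit.
#' @return A tibble of class `mtfr_modules`, one row per module: `scope`,
#'   `rank_index`, `importance`, list-columns `mirna_weights`,
#'   `mrna_weights` (named numeric), `selected_mirnas`, `selected_mrnas`
#'   (character), and counts `n_mirnas`, `n_mrnas`.
#' @export
extract_modules <- function(fit, mirna_ids = NULL, mrna_ids = NULL,
                            cohort_names = NULL) {
  params <- if (inherits(fit, "mtfr_fit")) fit$params else fit
  mirna_ids <- mirna_ids %||% fit$mirna_ids
  mrna_ids <- mrna_ids %||% fit$mrna_ids
  cohort_names <- cohort_names %||% fit$cohort_names
  dec <- decompose_params(params, cohort_names)
  rows <- purrr::map(dec, function(d) {
    R <- length(d$importance)
    if (R == 0L) return(NULL)
    purrr::map(seq_len(R), function(r) {
      wx <- stats::setNames(d$WX_tilde[, r], mirna_ids)
      wy <- stats::setNames(d$WY_tilde[r, ], mrna_ids)
      tibble::tibble(
        scope = d$scope, rank_index = r, importance = d$importance[r],
        mirna_weights = list(wx), mrna_weights = list(wy),
        selected_mirnas = list(select_features(wx)),
        selected_mrnas = list(select_features(wy))
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(out)) {
    out$n_mirnas <- lengths(out$selected_mirnas)
    out$n_mrnas <- lengths(out$selected_mrnas)
  } else {
    out <- tibble::tibble(scope = character(), rank_index = integer(),
                          importance = numeric(), mirna_weights = list(),
                          mrna_weights = list(), selected_mirnas = list(),
                          selected_mrnas = list(), n_mirnas = integer(),
                          n_mrnas = integer())
  }
  class(out) <- c("mtfr_modules", class(out))
  out
}

#' Long-format module weights
#'
#' Unnests the per-module weight vectors into one row per (module, feature),
#' convenient for plotting and export.
#'
#' @param modules An `mtfr_modules` tibble.
#' @param side `"mirna"` or `"mrna"`.
#' @return Tibble: `scope`, `rank_index`, `feature`, `weight`, `selected`.
#' @export
module_weights <- function(modules, side = c("mirna", "mrna")) {
  side <- match.arg(side)
  wcol <- paste0(side, "_weights")
  scol <- paste0("selected_", side, "s")
  purrr::pmap_dfr(
    list(modules$scope, modules$rank_index, modules[[wcol]], modules[[scol]]),
    function(scope, rank_index, w, sel) {
      tibble::tibble(scope = scope, rank_index = rank_index,
                     feature = names(w), weight = unname(w),
                     selected = names(w) %in% sel)
    }
  )
}

#' Write modules to a directory of TSVs plus a JSON summary
#'
#' @param modules An `mtfr_modules` tibble.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_modules <- function(modules, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (side in c("mirna", "mrna")) {
    ww <- module_weights(modules, side)
    utils::write.table(ww, file.path(dir, paste0("module_", side, "_weights.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- modules[, c("scope", "rank_index", "importance", "n_mirnas", "n_mrnas")]
  jsonlite::write_json(summary, file.path(dir, "modules_summary.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(dir)
}
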