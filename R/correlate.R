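# Spearman rank-correlation matrices across factor scores and covariates
# (rank-based because several neuropsychological scores are heavily
# skewed). Pairwise-complete handling; constant variables give flagged
# NA cells rather than errors.

#' Rank-correlation matrix over a variable set
#'
#' @param records data.frame holding the variables.
#' @param vars Character vector of column names (>= 2).
#' @param method Correlation method; \code{"spearman"} (default) or
#'   \code{"pearson"}.
#' @param min_pairs Minimum complete pairs per cell (default 3); cells
#'   with fewer are NA.
#' @return Symmetric correlation matrix with unit diagonal. Cells
#'   involving a constant variable are NA; the offending variables are
#'   listed in the \code{"constant_vars"} attribute.
#' @export
correlation_matrix <- function(records, vars,
                               method = c("spearman", "pearson"),
                               min_pairs = 3L) {
  method <- match.arg(method)
  df <- as.data.frame(records)
  missing_v <- setdiff(vars, names(df))
  if (length(missing_v))
    stop("records lack variable(s): ", paste(missing_v, collapse = ", "))
  if (length(vars) < 2L) stop("need at least two variables")
  X <- df[vars]
  k <- length(vars)
  M <- diag(1, k)
  dimnames(M) <- list(vars, vars)
  constants <- character(0)
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    ok <- complete.cases(X[[i]], X[[j]])
    if (sum(ok) < min_pairs) {
      M[i, j] <- M[j, i] <- NA_real_
      next
    }
    xi <- X[[i]][ok]; xj <- X[[j]][ok]
    if (length(unique(xi)) < 2L || length(unique(xj)) < 2L) {
      M[i, j] <- M[j, i] <- NA_real_
      constants <- union(constants,
                         vars[c(i, j)][c(length(unique(xi)) < 2L,
                                         length(unique(xj)) < 2L)])
      next
    }
    M[i, j] <- M[j, i] <- cor(xi, xj, method = method)
  }
  attr(M, "constant_vars") <- constants
  M
}
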