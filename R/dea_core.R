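#' Construct a set of decision-making units (DMUs)
#'
#' Bundles the input and output vectors of \code{n} decision-making units
#' into the container consumed by the CCR solvers.  In the obesity
#' application each subject is one DMU with two inputs (physical-activity
#' expenditure in METs-h/day and the inverse of caloric intake in day/kcal)
#' and one output (the inverse of body mass index, m\eqn{^2}/kg), but the
#' container is dimension-generic.
#'
#' @param ids character or coercible vector of unique DMU identifiers.
#' @param inputs numeric matrix, \code{n x m}, strictly positive; one row
#'   per DMU, one column per input.
#' @param outputs numeric matrix, \code{n x s}, strictly positive.
#' @return An object of class \code{"dmu_set"}: a list with elements
#'   \code{ids}, \code{inputs} (\code{n x m}) and \code{outputs}
#'   (\code{n x s}).
#' @seealso [solve_ccr()], [efficiency_scores()], [build_dea_frame()]
#' @export
dmu_set <- function(ids, inputs, outputs) {
  inputs  <- as.matrix(inputs)
  outputs <- as.matrix(outputs)
  storage.mode(inputs)  <- "double"
  storage.mode(outputs) <- "double"
  ids <- as.character(ids)
  n <- length(ids)
  if (n < 1L) stop("a dmu_set needs at least one DMU")
  if (anyDuplicated(ids)) {
    stop("duplicate DMU ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (nrow(inputs) != n || nrow(outputs) != n) {
    stop("inputs and outputs must have one row per DMU id")
  }
  check_positive_rows(inputs, ids, "input")
  check_positive_rows(outputs, ids, "output")
  structure(
    list(ids = ids, inputs = inputs, outputs = outputs),
    class = "dmu_set"
  )
}

check_positive_rows <- function(mat, ids, what) {
  bad <- !is.finite(mat) | mat <= 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("DMU '%s': %s_%d must be strictly positive and finite (got %s)",
                 ids[idx[1L]], what, idx[2L], format(mat[idx[1L], idx[2L]])))
  }
  invisible(TRUE)
}

#' @export
print.dmu_set <- function(x, ...) {
  cat(sprintf("<dmu_set: %d DMUs, %d input(s), %d output(s)>\n",
              length(x$ids), ncol(x$inputs), ncol(x$outputs)))
  invisible(x)
}

#' Solver options for the CCR linear programs
#'
#' @param tol feasibility tolerance used when checking the envelopment
#'   constraints at the optimum.
#' @param efficient_tol scores within this distance of 1 are reported as
#'   exactly efficient (theta = 1).
#' @param lambda_tol peer weights above this threshold enter the reference
#'   set.
#' @param rescale if \code{TRUE} (default) every input and output column is
#'   internally rescaled to unit mean before the LP is solved.  CCR scores
#'   are invariant to units, so this changes no score, but it keeps the LP
#'   well conditioned when columns differ by several orders of magnitude
#'   (inverse intake is about 4e-4 day/kcal while expenditure is about 36
#'   METs-h/day).
#' @return A list of class \code{"solver_options"}.
#' @export
solver_options <- function(tol = 1e-9, efficient_tol = 1e-6,
                           lambda_tol = 1e-7, rescale = TRUE) {
  stopifnot(tol > 0, efficient_tol > 0, lambda_tol > 0, is.logical(rescale))
  structure(list(tol = tol, efficient_tol = efficient_tol,
                 lambda_tol = lambda_tol, rescale = rescale),
            class = "solver_options")
}

# column-rescale inputs/outputs to unit mean (valid by units invariance)
rescale_columns <- function(dmus) {
  sx <- colMeans(dmus$inputs)
  sy <- colMeans(dmus$outputs)
  list(
    X = sweep(dmus$inputs, 2L, sx, "/"),
    Y = sweep(dmus$outputs, 2L, sy, "/")
  )
}

dmu_index <- function(dmus, target_id) {
  o <- match(as.character(target_id), dmus$ids)
  if (is.na(o)) stop("target_id '", target_id, "' is not in the DMU set")
  o
}

#' Solve the input-oriented CCR envelopment program for one DMU
#'
#' Minimises the radial input-contraction factor \eqn{\theta} subject to the
#' constant-returns-to-scale envelopment constraints
#' \deqn{\sum_j \lambda_j x_{ij} \le \theta x_{io} \quad (i = 1..m), \qquad
#'       \sum_j \lambda_j y_{rj} \ge y_{ro} \quad (r = 1..s), \qquad
#'       \lambda \ge 0.}
#' The target DMU always envelops itself (\eqn{\lambda_o = 1, \theta = 1}),
#' so the program is feasible for any valid data and the optimum satisfies
#' \eqn{0 < \theta^* \le 1}.
#'
#' @param dmus a [dmu_set()].
#' @param target_id id of the DMU to score.
#' @param options a [solver_options()] list.
#' @return A list of class \code{"ccr_result"} with elements \code{dmu_id},
#'   \code{theta} (reported score in (0, 1]), \code{theta_raw} (unclipped LP
#'   optimum), \code{lambdas} (named peer weights), \code{reference_set}
#'   (ids with weight above \code{lambda_tol}) and \code{solver_status}
#'   (\code{"optimal"} or \code{"numerical_failure"}).
#' @examples
#' d <- dmu_set(c("A", "B"), inputs = cbind(c(2, 4)), outputs = cbind(c(2, 2)))
#' solve_ccr(d, "B")$theta  # 0.5: B could halve its input and stay feasible
#' @export
solve_ccr <- function(dmus, target_id, options = solver_options()) {
  stopifnot(inherits(dmus, "dmu_set"))
  o <- dmu_index(dmus, target_id)
  n <- length(dmus$ids)

  if (n == 1L) {
    return(ccr_result(dmus$ids[o], theta_raw = 1,
                      lambdas = stats::setNames(1, dmus$ids[o]),
                      status = "optimal", options = options))
  }

  sc <- if (options$rescale) rescale_columns(dmus) else
    list(X = dmus$inputs, Y = dmus$outputs)
  X <- t(sc$X)  # m x n
  Y <- t(sc$Y)  # s x n

  # decision vector: (theta, lambda_1..lambda_n), all >= 0
  obj <- c(1, rep(0, n))
  A_le <- cbind(-X[, o, drop = FALSE], X)   # sum lambda x - theta x_o <= 0
  b_le <- rep(0, nrow(X))
  A_ge <- cbind(rep(0, nrow(Y)), Y)         # sum lambda y >= y_o
  b_ge <- Y[, o]

  sol <- boot::simplex(a = obj, A1 = A_le, b1 = b_le, A2 = A_ge, b2 = b_ge,
                       n.iter = 50L * (n + 6L), eps = options$tol)
  if (sol$solved != 1L) {
    return(ccr_result(dmus$ids[o], theta_raw = NA_real_,
                      lambdas = stats::setNames(rep(NA_real_, n), dmus$ids),
                      status = "numerical_failure", options = options))
  }
  theta   <- unname(sol$soln[1L])
  lambdas <- stats::setNames(unname(sol$soln[-1L]), dmus$ids)

  # verify envelopment feasibility at the reported optimum
  slack_in  <- as.vector(X %*% lambdas) - theta * X[, o]
  slack_out <- as.vector(Y %*% lambdas) - Y[, o]
  ftol <- max(options$tol * 1e3, 1e-7)
  if (any(slack_in > ftol) || any(slack_out < -ftol)) {
    return(ccr_result(dmus$ids[o], theta_raw = theta, lambdas = lambdas,
                      status = "numerical_failure", options = options))
  }
  ccr_result(dmus$ids[o], theta_raw = theta, lambdas = lambdas,
             status = "optimal", options = options)
}

ccr_result <- function(id, theta_raw, lambdas, status, options) {
  theta <- theta_raw
  if (status == "optimal") {
    if (theta >= 1 - options$efficient_tol) theta <- 1
    theta <- min(max(theta, 1e-12), 1)
  }
  refs <- names(lambdas)[!is.na(lambdas) & lambdas > options$lambda_tol]
  structure(
    list(dmu_id = id, theta = theta, theta_raw = theta_raw,
         lambdas = lambdas, reference_set = refs, solver_status = status),
    class = "ccr_result"
  )
}

#' @export
print.ccr_result <- function(x, ...) {
  cat(sprintf("<ccr_result %s: theta = %.6f [%s], peers: %s>\n",
              x$dmu_id, x$theta, x$solver_status,
              paste(x$reference_set, collapse = ", ")))
  invisible(x)
}

#' Solve the multiplier (dual) form of the input-oriented CCR program
#'
#' Maximises the virtual output \eqn{u^\top y_o} subject to
#' \eqn{v^\top x_o = 1}, \eqn{u^\top y_j - v^\top x_j \le 0} for every DMU
#' \eqn{j}, and \eqn{u, v \ge 0}.  By LP duality its optimum equals the
#' envelopment-form score from [solve_ccr()]; the package uses it as an
#' internal verification oracle rather than for production scoring (the
#' envelopment form yields the peer weights directly).
#'
#' @inheritParams solve_ccr
#' @return A \code{"ccr_result"}; \code{lambdas} holds the optimal
#'   multipliers \code{(v, u)} instead of peer weights and
#'   \code{reference_set} is empty.
#' @export
solve_ccr_multiplier <- function(dmus, target_id, options = solver_options()) {
  stopifnot(inherits(dmus, "dmu_set"))
  o <- dmu_index(dmus, target_id)
  n <- length(dmus$ids)
  if (n == 1L) {
    return(ccr_result(dmus$ids[o], theta_raw = 1,
                      lambdas = stats::setNames(1, dmus$ids[o]),
                      status = "optimal", options = options))
  }
  sc <- if (options$rescale) rescale_columns(dmus) else
    list(X = dmus$inputs, Y = dmus$outputs)
  X <- t(sc$X); Y <- t(sc$Y)
  m <- nrow(X); s <- nrow(Y)

  # decision vector: (v_1..v_m, u_1..u_s), all >= 0; maximize u.y_o
  obj <- c(rep(0, m), Y[, o])
  A_le <- cbind(-t(X), t(Y))        # u.y_j - v.x_j <= 0
  b_le <- rep(0, n)
  A_eq <- matrix(c(X[, o], rep(0, s)), nrow = 1L)  # v.x_o = 1
  b_eq <- 1

  sol <- boot::simplex(a = obj, A1 = A_le, b1 = b_le, A3 = A_eq, b3 = b_eq,
                       maxi = TRUE, n.iter = 50L * (n + m + s + 4L),
                       eps = options$tol)
  if (sol$solved != 1L) {
    return(ccr_result(dmus$ids[o], theta_raw = NA_real_,
                      lambdas = stats::setNames(rep(NA_real_, m + s),
                                                c(paste0("v", seq_len(m)),
                                                  paste0("u", seq_len(s)))),
                      status = "numerical_failure", options = options))
  }
  mult <- stats::setNames(unname(sol$soln),
                          c(paste0("v", seq_len(m)), paste0("u", seq_len(s))))
  res <- ccr_result(dmus$ids[o], theta_raw = unname(sol$value),
                    lambdas = mult, status = "optimal", options = options)
  res$reference_set <- character(0)
  res
}

#' Batch CCR efficiency scores
#'
#' Solves one input-oriented CCR program per DMU and returns the vector of
#' efficiency scores.  On every valid set the maximum score is 1 (the
#' frontier is always attained) and scores are independent of the order in
#' which DMUs are listed.
#'
#' @inheritParams solve_ccr
#' @return Named numeric vector of scores in (0, 1], one per DMU id.
#' @export
efficiency_scores <- function(dmus, options = solver_options()) {
  stopifnot(inherits(dmus, "dmu_set"))
  out <- vapply(dmus$ids, function(id) {
    res <- solve_ccr(dmus, id, options)
    if (res$solver_status != "optimal") {
      stop("CCR solver failed for DMU '", id, "' (", res$solver_status, ")")
    }
    res$theta
  }, numeric(1L))
  stats::setNames(out, dmus$ids)
}

#' Read / write a DMU set as CSV
#'
#' The on-disk format has a mandatory header
#' \code{dmu_id, input_1..input_m, output_1..output_s}.
#'
#' @param path file path.
#' @return \code{read_dmu_csv}: a [dmu_set()].
#' @export
read_dmu_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  in_cols  <- grep("^input_[0-9]+$",  names(df), value = TRUE)
  out_cols <- grep("^output_[0-9]+$", names(df), value = TRUE)
  if (!"dmu_id" %in% names(df) || length(in_cols) == 0L || length(out_cols) == 0L) {
    stop("DMU CSV must have columns dmu_id, input_1.., output_1..")
  }
  dmu_set(df$dmu_id,
          as.matrix(df[in_cols [order(as.integer(sub("input_",  "", in_cols)))]]),
          as.matrix(df[out_cols[order(as.integer(sub("output_", "", out_cols)))]]))
}

#' @rdname read_dmu_csv
#' @param dmus a [dmu_set()] to serialise.
#' @export
write_dmu_csv <- function(dmus, path) {
  stopifnot(inherits(dmus, "dmu_set"))
  df <- data.frame(dmu_id = dmus$ids, check.names = FALSE)
  X <- dmus$inputs; Y <- dmus$outputs
  colnames(X) <- paste0("input_",  seq_len(ncol(X)))
  colnames(Y) <- paste0("output_", seq_len(ncol(Y)))
  utils::write.csv(cbind(df, X, Y), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
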