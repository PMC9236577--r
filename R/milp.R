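#' @title Mixed-integer linear programming backend
#'
#' @description
#' Internal model layer used by the U-step linear program, the C-step ILP and
#' the clone-matching assignment problem. Models are assembled incrementally
#' as sparse constraint triplets and solved with the HiGHS solver (via the
#' bundled SciPy helper script run through the system `python` interpreter,
#' which ships in the same environment as this package).
#'
#' Infinite bounds are encoded as +/- 1e30, which HiGHS treats as infinite.
#'
#' @name milp-backend
#' @keywords internal
NULL

.MILP_INF <- 1e30

#' Create an empty MILP model
#' @return an environment holding variables, bounds and constraint triplets.
#' @keywords internal
#' @noRd
milp_model <- function() {
  m <- new.env(parent = emptyenv())
  m$nvar <- 0L
  m$lb <- numeric()
  m$ub <- numeric()
  m$obj <- numeric()
  m$int <- integer()
  m$cons_ind <- list()
  m$cons_val <- list()
  m$cons_lb <- numeric()
  m$cons_ub <- numeric()
  m
}

#' Add a block of variables, returning their column indices
#' @noRd
milp_add_vars <- function(m, n, lb = 0, ub = Inf, type = c("C", "I", "B"),
                          obj = 0) {
  type <- match.arg(type)
  if (type == "B") {
    lb <- pmax(lb, 0)
    ub <- pmin(ub, 1)
  }
  idx <- m$nvar + seq_len(n)
  m$nvar <- m$nvar + as.integer(n)
  m$lb <- c(m$lb, rep_len(as.numeric(lb), n))
  m$ub <- c(m$ub, rep_len(as.numeric(ub), n))
  m$obj <- c(m$obj, rep_len(as.numeric(obj), n))
  m$int <- c(m$int, rep_len(if (type == "C") 0L else 1L, n))
  idx
}

#' Fix a variable to a constant via its bounds
#' @noRd
milp_fix <- function(m, idx, value) {
  m$lb[idx] <- value
  m$ub[idx] <- value
  invisible(m)
}

#' Add one linear constraint lb <= sum(val * x[ind]) <= ub
#'
#' Repeated indices are summed by the sparse assembly on the solver side, but
#' callers collapse duplicates for clarity.
#' @noRd
milp_add_constr <- function(m, ind, val, lb = -Inf, ub = Inf) {
  k <- length(m$cons_lb) + 1L
  m$cons_ind[[k]] <- as.integer(ind)
  m$cons_val[[k]] <- as.numeric(val)
  m$cons_lb[k] <- lb
  m$cons_ub[k] <- ub
  invisible(m)
}

#' Locate a python interpreter with scipy available
#' @noRd
milp_python <- function() {
  cand <- getOption("clonedecomp.python", Sys.getenv("CLONEDECOMP_PYTHON", ""))
  if (!nzchar(cand)) cand <- Sys.which("python3")
  if (!nzchar(cand)) cand <- Sys.which("python")
  if (!nzchar(cand)) {
    stop("no python interpreter found for the MILP backend; set ",
         "options(clonedecomp.python = ...)", call. = FALSE)
  }
  cand
}

#' Solve an assembled model
#'
#' @param m model environment from [milp_model()].
#' @param time_limit wall-clock limit in seconds, or `NULL` for none.
#' @param mip_gap relative MIP gap tolerance, or `NULL` for solver default.
#' @return list with `status` (one of "optimal", "limit", "infeasible",
#'   "unbounded", "failed"), `objective`, and the primal solution `x`
#'   (`NULL` when no incumbent exists).
#' @keywords internal
#' @noRd
milp_solve <- function(m, time_limit = NULL, mip_gap = NULL) {
  cap <- function(x) {
    x[x > .MILP_INF] <- .MILP_INF
    x[x < -.MILP_INF] <- -.MILP_INF
    x
  }
  nrow <- length(m$cons_lb)
  payload <- list(
    ncol = m$nvar,
    obj = cap(m$obj),
    lb = cap(m$lb),
    ub = cap(m$ub),
    integrality = m$int,
    nrow = nrow,
    row = if (nrow) rep.int(seq_len(nrow), lengths(m$cons_ind)) else integer(),
    col = if (nrow) unlist(m$cons_ind, use.names = FALSE) else integer(),
    val = if (nrow) unlist(m$cons_val, use.names = FALSE) else numeric(),
    clb = cap(m$cons_lb),
    cub = cap(m$cons_ub),
    time_limit = time_limit,
    mip_gap = mip_gap
  )
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  script <- system.file("python", "milp_solve.py", package = "clonedecomp")
  if (!nzchar(script)) stop("bundled MILP helper script not found")
  out <- system2(milp_python(), c(script, fin, fout),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!file.exists(fout) || (!is.null(status) && status != 0)) {
    stop("MILP backend failed: ", paste(out, collapse = "\n"), call. = FALSE)
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  status_map <- c(`0` = "optimal", `1` = "limit", `2` = "infeasible",
                  `3` = "unbounded", `4` = "failed")
  list(
    status = unname(status_map[as.character(res$status)]),
    message = res$message,
    objective = res$objective,
    x = res$x
  )
}
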