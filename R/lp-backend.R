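# Linear-programming backend.
#
# The solvers in this package reduce everything to one contract:
# maximize/minimize c'x subject to A_ub x <= b_ub, A_eq x = b_eq,
# lb <= x <= ub, returning (status, objective, x). The default backend is
# HiGHS, driven through SciPy's linprog in a short Python helper shipped
# with the package; problems and results travel as JSON files.

lp_cache <- new.env(parent = emptyenv())

find_python <- function() {
  if (!is.null(lp_cache$python)) return(lp_cache$python)
  candidates <- c(
    getOption("ramtool.python", ""),
    Sys.getenv("RAMTOOL_PYTHON", ""),
    Sys.which("python"), Sys.which("python3")
  )
  candidates <- candidates[nzchar(candidates)]
  for (py in candidates) {
    ok <- tryCatch(
      system2(py, c("-c", shQuote("import scipy.optimize")),
              stdout = FALSE, stderr = FALSE) == 0,
      error = function(e) FALSE, warning = function(w) FALSE
    )
    if (isTRUE(ok)) {
      lp_cache$python <- py
      return(py)
    }
  }
  abort(paste0(
    "No Python interpreter with scipy found. Set options(ramtool.python=) ",
    "or the RAMTOOL_PYTHON environment variable to one."
  ))
}

sparse_triplet <- function(A) {
  if (is.null(A) || nrow(A) == 0) return(NULL)
  A <- methods::as(methods::as(Matrix(A, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  list(i = A@i, j = A@j, x = A@x, nrow = nrow(A), ncol = ncol(A))
}

#' Solve a linear program
#'
#' Thin wrapper over the package's LP backend (HiGHS via SciPy). Used by the
#' deFBA and RBA solvers; exported for inspection of the discretized
#' problems.
#'
#' @param objective Objective coefficient vector.
#' @param A_ub,b_ub Inequality constraints `A_ub x <= b_ub` (may be `NULL`).
#' @param A_eq,b_eq Equality constraints (may be `NULL`).
#' @param lb,ub Variable bounds (recycled; `-Inf`/`Inf` allowed).
#' @param maximize Maximize instead of minimize.
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   ...), `objective` and `x` (both `NULL` unless optimal).
#' @export
lp_solve <- function(objective, A_ub = NULL, b_ub = NULL,
                     A_eq = NULL, b_eq = NULL,
                     lb = 0, ub = Inf, maximize = FALSE) {
  n <- length(objective)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  clamp <- function(x) {
    x[x == Inf] <- 1e30; x[x == -Inf] <- -1e30; x
  }
  prob <- list(
    sense = if (maximize) "max" else "min",
    c = as.numeric(objective),
    A_ub = sparse_triplet(A_ub),
    b_ub = if (is.null(b_ub)) NULL else as.numeric(b_ub),
    A_eq = sparse_triplet(A_eq),
    b_eq = if (is.null(b_eq)) NULL else as.numeric(b_eq),
    lb = clamp(as.numeric(lb)), ub = clamp(as.numeric(ub))
  )
  in_path <- tempfile("lp_", fileext = ".json")
  out_path <- tempfile("lp_", fileext = ".json")
  on.exit(unlink(c(in_path, out_path)), add = TRUE)
  jsonlite::write_json(prob, in_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  script <- system.file("python", "lp_solve.py", package = "ramtool",
                        mustWork = TRUE)
  status <- system2(find_python(), c(script, in_path, out_path),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(out_path)) {
    abort(paste0("LP backend failed: ", paste(status, collapse = "\n")))
  }
  res <- jsonlite::read_json(out_path, simplifyVector = TRUE)
  list(status = res$status, objective = res$objective,
       x = if (is.null(res$x)) NULL else as.numeric(res$x))
}
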