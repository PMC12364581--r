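# Enumeration and counting of the monotone Boolean functions (MBFs)
# compatible with a toggle-n network.
#
# All edges of a toggle network are inhibitory, so a compatible update
# function for any node is a Boolean function of the other n-1 node values
# that is DECREASING in every input. The number of monotone functions of s
# inputs is the Dedekind number D(s); decreasing functions are in bijection
# with increasing ones via complementation of the inputs, so both families
# have D(s) members. Enumeration proceeds over the increasing family as
# down-set extension on the Boolean lattice: truth-table positions are
# visited in numeric order (every subset of a position precedes it), and a
# position may take value 0 only when all its immediate predecessors are 0.
#
# States here live in {0, 1}^n (the MBF convention); 1 corresponds to the
# high (+1) level of the Ising dynamics and 0 to low (-1).

# Enumerate all increasing monotone Boolean functions of n_inputs variables.
# Returns a 0/1 matrix with one row per function and one column per input
# point; column b + 1 is the point whose bit i (1-based input i = 2^(i-1))
# encodes the i-th input. Row count is D(n_inputs).
.enumerate_increasing <- function(n_inputs) {
  np <- 2L^n_inputs
  preds <- vector("list", np)
  for (b in seq_len(np) - 1L) {
    bits <- which(bitwAnd(b, 2L^(seq_len(n_inputs) - 1L)) > 0L)
    preds[[b + 1L]] <- b - 2L^(bits - 1L) + 1L # 1-based predecessor columns
  }
  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 0)
  val <- integer(np)
  rec <- function(pos) {
    if (pos > np) {
      acc$rows[[length(acc$rows) + 1L]] <- val
      return(invisible())
    }
    lo <- if (length(preds[[pos]])) max(val[preds[[pos]]]) else 0L
    if (lo == 0L) {
      val[pos] <<- 0L
      rec(pos + 1L)
    }
    val[pos] <<- 1L
    rec(pos + 1L)
    val[pos] <<- 0L
  }
  rec(1L)
  do.call(rbind, acc$rows)
}

#' Enumerate all decreasing monotone Boolean functions
#'
#' A Boolean function of `n_inputs` variables is decreasing (antitone) when
#' raising any input from 0 to 1 never raises the output. These are the
#' update functions compatible with the all-inhibitory edges of a toggle
#' network. The count equals the Dedekind number `D(n_inputs)`; enumeration
#' is by down-set extension of the Boolean lattice on the complemented
#' inputs, and is supported up to 5 inputs (`D(5) = 7581`); beyond that the
#' family is combinatorially infeasible to enumerate.
#'
#' @param n_inputs number of inputs, 0..5
#' @return 0/1 matrix, one row per function, one column per input point;
#'   column `b + 1` holds the output at the input whose i-th coordinate is
#'   bit `2^(i-1)` of `b`
#' @examples
#' nrow(enumerate_decreasing_mbfs(2)) # D(2) = 6
#' @export
enumerate_decreasing_mbfs <- function(n_inputs) {
  n_inputs <- as.integer(n_inputs)
  if (is.na(n_inputs) || n_inputs < 0)
    stop("n_inputs must be a non-negative integer")
  if (n_inputs > 5)
    stop("enumeration of monotone Boolean functions is infeasible beyond ",
         "5 inputs (the Dedekind numbers grow too quickly)")
  inc <- .enumerate_increasing(n_inputs)
  # f decreasing <=> b -> f(complement(b)) increasing; complementing the
  # input index reverses the column order
  dec <- inc[, rev(seq_len(ncol(inc))), drop = FALSE]
  colnames(dec) <- NULL
  dec
}

#' Dedekind number
#'
#' Number of monotone Boolean functions of `s` inputs, computed by
#' enumeration (supported for `s <= 5`).
#'
#' @param s number of inputs, 0..5
#' @return integer count
#' @export
dedekind_number <- function(s) nrow(enumerate_decreasing_mbfs(s))

#' Count decreasing functions by output at canonical inputs
#'
#' For the toggle-n network every node's update is a decreasing function of
#' the `n - 1` other node values, and such functions are invariant under
#' input permutations of the enumerated family's counts: how many functions
#' produce output 0 (or 1) at an input depends only on the number of ones in
#' that input. `u_n(j)` counts the decreasing functions of `n - 1` inputs
#' whose output at the canonical input with `j` ones (`1...10...0`) is 0,
#' and `v_n(j)` those with output 1; `u_n(j) + v_n(j) = D(n-1)` for every j.
#'
#' @param n toggle network size, 2..6
#' @return an object of class `mbf_count_table` with fields `n`, `u`, `v`
#'   (length-`n` vectors indexed by `j = 0..n-1`) and `dedekind`
#' @examples
#' compute_uv_table(4)$u # 1 6 14 19
#' @export
compute_uv_table <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2 || n > 6)
    stop("u/v tables are defined for toggle sizes 2..6")
  dec <- enumerate_decreasing_mbfs(n - 1L)
  js <- 0:(n - 1L)
  # canonical input with j ones = (1,...,1,0,...,0), index 2^j - 1
  u <- vapply(js, function(j) sum(dec[, 2L^j] == 0L), numeric(1))
  v <- nrow(dec) - u
  structure(list(n = n, u = setNames(u, paste0("j", js)),
                 v = setNames(v, paste0("j", js)), dedekind = nrow(dec)),
            class = "mbf_count_table")
}

#' @export
print.mbf_count_table <- function(x, ...) {
  cat("MBF output counts for the toggle-", x$n, " network (D(",
      x$n - 1, ") = ", x$dedekind, ")\n", sep = "")
  df <- data.frame(ones_in_input = 0:(x$n - 1), u = unname(x$u),
                   v = unname(x$v))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Count MBF tuples supporting each k-high fixed point of a toggle network
#'
#' `phi_k` is the number of tuples `f = (f_1, ..., f_n)` of decreasing
#' functions for which the canonical state with `k` ones is a fixed point of
#' the toggle-n update. Each of the k high nodes sees `k - 1` ones among its
#' `n - 1` inputs and must output 1, and each low node sees `k` ones and
#' must output 0, giving the product form
#' `phi_k = v_n(k-1)^k * u_n(k)^(n-k)` (with `phi_0 = phi_n = 1`).
#'
#' Counts are returned as doubles; for `n = 6` the middle entries exceed
#' 2^53 and are then correct only to double precision, so the exact factored
#' form is attached as the `"factors"` attribute.
#'
#' @param n toggle network size, 2..6
#' @return named numeric vector `phi0..phin`, with a `"factors"` attribute
#'   giving the exact `v^k * u^(n-k)` factorization per k
#' @examples
#' phi_vector(2) # 1 4 1
#' @seealso [brute_force_phi()] for the independent exhaustive oracle
#' @export
phi_vector <- function(n) {
  uv <- compute_uv_table(n)
  ks <- 0:n
  u <- unname(uv$u)
  v <- unname(uv$v)
  phi <- vapply(ks, function(k) {
    if (k == 0) return(u[1]^n)
    if (k == n) return(v[n]^n)
    v[k]^k * u[k + 1]^(n - k) # v_n(k-1), u_n(k): 1-based vectors
  }, numeric(1))
  names(phi) <- paste0("phi", ks)
  attr(phi, "factors") <- lapply(ks, function(k) {
    if (k == 0) list(base = c(u = u[1]), exp = c(n))
    else if (k == n) list(base = c(v = v[n]), exp = c(n))
    else list(base = c(v = v[k], u = u[k + 1]), exp = c(k, n - k))
  })
  phi
}

#' Brute-force count of MBF tuples supporting k-high fixed points
#'
#' Independent oracle for [phi_vector()]: explicitly forms every tuple of
#' decreasing functions (the tuple space has `D(n-1)^n` members, 9 for
#' n = 2 and 216 for n = 3), tests the fixed-point condition
#' `f_j(E_k without node j) = E_k[j]` at the canonical state `E_k` for every
#' k, and tallies. Limited to `n <= 3`.
#'
#' @param n toggle network size, 2 or 3
#' @return named numeric vector `phi0..phin`
#' @export
brute_force_phi <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2 || n > 3)
    stop("brute force supported for n = 2, 3 only")
  dec <- enumerate_decreasing_mbfs(n - 1L)
  nf <- nrow(dec)
  tuples <- as.matrix(expand.grid(rep(list(seq_len(nf)), n)))
  phi <- numeric(n + 1)
  for (k in 0:n) {
    Ek <- c(rep(1L, k), rep(0L, n - k))
    ok <- rep(TRUE, nrow(tuples))
    for (j in seq_len(n)) {
      inputs <- Ek[-j]
      idx <- sum(inputs * 2L^(seq_along(inputs) - 1L)) + 1L
      ok <- ok & dec[tuples[, j], idx] == Ek[j]
    }
    phi[k + 1] <- sum(ok)
  }
  setNames(phi, paste0("phi", 0:n))
}
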