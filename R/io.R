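# Plain-text interchange: long-format count/covariate CSVs and adjacency
# as either an edge list (site_a,site_b) or a dense 0/1 matrix with a
# site-id header row.

#' Read a long-format count panel
#'
#' Expects columns `site_id,time,count`; sites become rows ordered by first
#' appearance (or `site_ids` when given), times must be 1..T.
#'
#' @param path CSV file.
#' @param site_ids optional ordering of sites.
#' @return n x T integer matrix with site-id rownames.
#' @export
read_counts_csv <- function(path, site_ids = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "time", "count")
  if (!all(need %in% names(d))) stop("counts CSV needs columns site_id,time,count")
  if (is.null(site_ids)) site_ids <- unique(as.character(d$site_id))
  times <- sort(unique(d$time))
  if (!identical(as.integer(times), seq_along(times)))
    stop("time must be 1..T without gaps")
  Y <- matrix(NA_integer_, length(site_ids), length(times),
              dimnames = list(site_ids, NULL))
  Y[cbind(match(as.character(d$site_id), site_ids), d$time)] <- as.integer(d$count)
  if (anyNA(Y)) stop("count panel has missing cells")
  if (any(Y < 0)) stop("counts must be non-negative")
  Y
}

#' Write a count panel in long format
#' @param Y n x T matrix with site-id rownames.
#' @param path output CSV.
#' @export
write_counts_csv <- function(Y, path) {
  ids <- rownames(Y); if (is.null(ids)) ids <- as.character(seq_len(nrow(Y)))
  d <- data.frame(site_id = rep(ids, times = ncol(Y)),
                  time = rep(seq_len(ncol(Y)), each = nrow(Y)),
                  count = as.vector(Y))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read adjacency from CSV
#'
#' Accepts an edge list with header `site_a,site_b`, or a dense 0/1 matrix
#' whose header row holds the site ids (asymmetric matrices are symmetrized
#' with a warning).
#'
#' @param path CSV file.
#' @param site_ids required for edge lists when isolated sites exist.
#' @return a [build_lattice()] lattice.
#' @export
read_adjacency_csv <- function(path, site_ids = NULL) {
  hdr <- names(utils::read.csv(path, nrows = 1L, check.names = FALSE))
  if (identical(hdr[1:2], c("site_a", "site_b"))) {
    e <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (is.null(site_ids)) site_ids <- unique(c(as.character(e$site_a),
                                                as.character(e$site_b)))
    build_lattice(cbind(e$site_a, e$site_b), site_ids)
  } else {
    m <- as.matrix(utils::read.csv(path, check.names = FALSE))
    as_lattice(m, site_ids = if (is.null(site_ids)) colnames(m) else site_ids)
  }
}

#' Write a lattice as an edge-list CSV
#' @param lattice a [build_lattice()] lattice.
#' @param path output CSV with header `site_a,site_b`.
#' @export
write_adjacency_csv <- function(lattice, path) {
  A <- lattice$N_raw
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  d <- data.frame(site_a = lattice$site_ids[idx[, 1]],
                  site_b = lattice$site_ids[idx[, 2]])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read covariate panels from long-format CSV
#'
#' Expects columns `site_id,time,name,value`. Spatial-only covariates use a
#' single time (or `NA`); temporal-only use a single site id `"*"`.
#'
#' @param path CSV file.
#' @param site_ids site ordering (required to place rows).
#' @param T_len panel horizon.
#' @return named list of [covariate_panel()] objects.
#' @export
read_covariates_csv <- function(path, site_ids, T_len) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "time", "name", "value")
  if (!all(need %in% names(d))) stop("covariate CSV needs columns site_id,time,name,value")
  n <- length(site_ids)
  out <- list()
  for (nm in unique(d$name)) {
    di <- d[d$name == nm, ]
    spatial_only <- all(is.na(di$time)) || length(unique(di$time)) == 1L
    temporal_only <- length(unique(di$site_id)) == 1L && all(di$site_id == "*")
    if (temporal_only) {
      v <- matrix(NA_real_, 1L, T_len)
      v[1L, di$time] <- di$value
    } else if (spatial_only) {
      v <- matrix(NA_real_, n, 1L)
      v[match(as.character(di$site_id), site_ids), 1L] <- di$value
    } else {
      v <- matrix(NA_real_, n, T_len)
      v[cbind(match(as.character(di$site_id), site_ids), di$time)] <- di$value
    }
    if (anyNA(v)) stop("covariate '", nm, "' has missing cells")
    out[[nm]] <- covariate_panel(nm, v)
  }
  out
}

#' Write covariate panels in long format
#' @param covariates named list of [covariate_panel()] objects.
#' @param site_ids site ids for the rows.
#' @param path output CSV.
#' @export
write_covariates_csv <- function(covariates, site_ids, path) {
  rows <- lapply(covariates, function(cv) {
    v <- cv$values
    if (nrow(v) == 1L) {
      data.frame(site_id = "*", time = seq_len(ncol(v)), name = cv$name,
                 value = as.vector(v))
    } else {
      data.frame(site_id = rep(site_ids[seq_len(nrow(v))], times = ncol(v)),
                 time = rep(seq_len(ncol(v)), each = nrow(v)), name = cv$name,
                 value = as.vector(v))
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write posterior draws to CSV
#' @param draws a [run_mcmc()] result.
#' @param path output CSV with columns chain,iter,eta,kappa,sigma,tau,sigma_eps,logpost.
#' @export
write_draws_csv <- function(draws, path) {
  utils::write.csv(as.data.frame(draws), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
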