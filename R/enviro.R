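.sd_env_vars <- c("annual_mean_temp", "mean_diurnal_range", "temp_seasonality",
                  "max_temp_warmest_month", "min_temp_coldest_month",
                  "annual_precip", "precip_warmest_quarter",
                  "precip_coldest_quarter", "gpp", "lai", "ndvi")

#' Read an occurrence-locality table
#'
#' CSV with header \code{locality_id,species,lon,lat[,elevation_m]}
#' (WGS84 decimal degrees).
#'
#' @param path Path to the CSV file.
#' @return Validated data frame of locality records.
#' @export
read_localities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_localities(df)
}

#' Validate locality records
#' @param df Data frame with \code{locality_id}, \code{species}, \code{lon},
#'   \code{lat}.
#' @return The validated data frame.
#' @export
validate_localities <- function(df) {
  need <- c("locality_id", "species", "lon", "lat")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("locality table lacks columns: ", paste(miss, collapse = ", "))
  if (any(df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90,
          na.rm = TRUE))
    stop("coordinates outside WGS84 bounds")
  if (anyNA(df$lon) || anyNA(df$lat)) stop("missing coordinates")
  df
}

#' Great-circle distance matrix in km
#'
#' Haversine distance on a sphere of radius 6371 km.
#' @param lon,lat Coordinate vectors in decimal degrees.
#' @return Square matrix of distances in km.
#' @export
haversine_km <- function(lon, lat) {
  n <- length(lon)
  m <- matrix(0, n, n)
  if (n > 1L) {
    p <- cbind(lon, lat)
    for (i in seq_len(n - 1L)) {
      d <- geosphere::distHaversine(p[i, , drop = FALSE],
                                    p[(i + 1L):n, , drop = FALSE],
                                    r = 6371000) / 1000
      m[i, (i + 1L):n] <- d
      m[(i + 1L):n, i] <- d
    }
  }
  m
}

#' Spatially thin occurrence records
#'
#' Implements the 5-km-buffer rule: conspecific localities closer than twice
#' the buffer radius (default < 10 km) are linked, and one representative per
#' connected component is retained, chosen at random under the given seed.
#' Localities of different species never interact.
#'
#' @param records Locality data frame (see \code{\link{read_localities}}).
#' @param radius_km Buffer radius in km (default 5; linking distance is
#'   \code{2 * radius_km}).
#' @param seed Integer seed for the random choice of representatives.
#' @return The retained locality rows, in original order.
#' @export
thin_localities <- function(records, radius_km = 5, seed) {
  records <- validate_localities(records)
  if (missing(seed)) stop("a seed is required for representative choice")
  set.seed(seed)
  keep <- logical(nrow(records))
  for (sp in unique(records$species)) {
    idx <- which(records$species == sp)
    d <- haversine_km(records$lon[idx], records$lat[idx])
    adj <- d < 2 * radius_km
    comp <- rep(0L, length(idx)); cur <- 0L
    for (s in seq_along(idx)) {
      if (comp[s] != 0L) next
      cur <- cur + 1L
      queue <- s; comp[s] <- cur
      while (length(queue) > 0L) {
        v <- queue[1L]; queue <- queue[-1L]
        nb <- which(adj[v, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    for (cc in seq_len(cur)) {
      members <- idx[comp == cc]
      keep[members[sample.int(length(members), 1L)]] <- TRUE
    }
  }
  records[keep, , drop = FALSE]
}

#' Read an environmental-variable matrix
#'
#' CSV with \code{locality_id}, \code{species} and the 11 environmental
#' variables (8 bioclimatic + GPP, LAI, NDVI) extracted at presence
#' localities.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame.
#' @export
read_env_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_env_matrix(df)
}

#' Validate an environmental matrix
#' @param df Data frame with id columns plus the 11 variables.
#' @return The validated data frame.
#' @export
validate_env_matrix <- function(df) {
  miss <- setdiff(.sd_env_vars, names(df))
  if (length(miss) > 0L)
    stop("environmental matrix lacks variables: ", paste(miss, collapse = ", "))
  if (anyNA(df[.sd_env_vars])) stop("missing values in environmental variables")
  df
}

#' Correlation-matrix PCA of environmental variables with Kaiser retention
#'
#' Standardizes the variables to z-scores, eigen-decomposes their correlation
#' matrix and retains components with eigenvalue > 1 (Kaiser criterion).
#' Loadings are principal-component loadings (eigenvector times the square
#' root of the eigenvalue), with each column's sign fixed so its
#' largest-magnitude loading is positive.
#'
#' @param env Environmental data frame (see \code{\link{read_env_matrix}}),
#'   or any data frame whose numeric non-id columns are the variables.
#' @param variables Variable columns (default the 11 standard ones when
#'   present, otherwise all numeric columns).
#' @return An object of class \code{env_pca}: \code{eigenvalues},
#'   \code{loadings} (variables x components), \code{explained_pct},
#'   \code{cumulative_pct}, \code{n_retained}, \code{scores} (rows x
#'   retained components), \code{species} (per row, if present).
#' @export
run_pca <- function(env, variables = NULL) {
  if (is.null(variables)) {
    variables <- if (all(.sd_env_vars %in% names(env))) .sd_env_vars
      else names(env)[vapply(env, is.numeric, logical(1L))]
  }
  X <- as.matrix(env[variables])
  if (nrow(X) < 2L) stop("PCA needs at least 2 rows")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate variable with zero variance: ",
         paste(variables[sds == 0], collapse = ", "))
  Z <- scale(X)
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  V <- eig$vectors
  lam <- pmax(eig$values, 0)
  loadings <- V %*% diag(sqrt(lam), length(lam))
  for (k in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      V[, k] <- -V[, k]
    }
  }
  dimnames(loadings) <- list(variables, paste0("PC", seq_along(lam)))
  ev <- explained_variance(lam, length(variables))
  n_ret <- sum(lam > 1)
  scores <- Z %*% V[, seq_len(max(n_ret, 1L)), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(eigenvalues = lam, loadings = loadings,
                 explained_pct = ev$explained_pct,
                 cumulative_pct = ev$cumulative_pct,
                 n_retained = n_ret, scores = scores,
                 species = if ("species" %in% names(env)) env$species else NULL),
            class = "env_pca")
}

#' Percent and cumulative explained variance from eigenvalues
#'
#' For a correlation-matrix PCA the eigenvalues sum to the number of
#' variables, so component k explains \code{100 * lambda_k / n_vars} percent.
#'
#' @param eigenvalues Non-negative eigenvalues, non-increasing.
#' @param n_vars Number of variables entering the PCA.
#' @return List with \code{explained_pct} and \code{cumulative_pct}.
#' @export
explained_variance <- function(eigenvalues, n_vars) {
  if (n_vars <= 0) stop("n_vars must be positive")
  if (any(eigenvalues < 0)) stop("eigenvalues must be non-negative")
  if (length(eigenvalues) > n_vars)
    stop("more eigenvalues than variables")
  expl <- 100 * eigenvalues / n_vars
  list(explained_pct = expl, cumulative_pct = cumsum(expl))
}

#' @export
print.env_pca <- function(x, digits = 3, ...) {
  cat(sprintf("Correlation-matrix PCA: %d variables, %d components retained (eigenvalue > 1)\n",
              nrow(x$loadings), x$n_retained))
  k <- max(x$n_retained, 1L)
  tab <- rbind(round(x$loadings[, seq_len(k), drop = FALSE], digits),
               Eigenvalue = round(x$eigenvalues[seq_len(k)], 3),
               `Cumulative variance (%)` = round(x$cumulative_pct[seq_len(k)], 2))
  print(tab)
  invisible(x)
}

#' Write Table-style PCA loadings and scores CSVs
#' @param x An \code{env_pca} object.
#' @param loadings_path,scores_path Output paths (either may be NULL).
#' @return Invisibly, the paths written.
#' @export
write_pca_csv <- function(x, loadings_path = NULL, scores_path = NULL) {
  stopifnot(inherits(x, "env_pca"))
  k <- max(x$n_retained, 1L)
  if (!is.null(loadings_path)) {
    tab <- as.data.frame(x$loadings[, seq_len(k), drop = FALSE])
    tab <- rbind(tab,
                 Eigenvalue = x$eigenvalues[seq_len(k)],
                 Cumulative_variance_pct = x$cumulative_pct[seq_len(k)])
    utils::write.csv(cbind(variable = rownames(tab), tab), loadings_path,
                     row.names = FALSE)
  }
  if (!is.null(scores_path)) {
    df <- as.data.frame(x$scores)
    if (!is.null(x$species)) df <- cbind(species = x$species, df)
    utils::write.csv(df, scores_path, row.names = FALSE)
  }
  invisible(c(loadings_path, scores_path))
}
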