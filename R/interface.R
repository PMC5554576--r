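read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Load a survival dataset from covariate and survival tables
#'
#' The survival table must have columns `id`, `time`, `status` (strictly
#' 0/1); the covariate table has an `id` first column and one numeric column
#' per feature.  Rows are aligned by id, so the two files may list samples
#' in different orders; a sample present in only one file is an error.
#'
#' @param cov_path Path to the covariate TSV/CSV.
#' @param surv_path Path to the survival TSV/CSV.
#' @param standardize Center and scale each feature to mean 0, sd 1
#'   (constant features are left centered only).
#' @return A [survival_dataset()].
#' @export
load_dataset <- function(cov_path, surv_path, standardize = TRUE) {
  surv <- read_table_auto(surv_path)
  if (!all(c("id", "time", "status") %in% names(surv)))
    stop("survival table needs columns 'id', 'time', 'status'")
  covs <- read_table_auto(cov_path)
  if (names(covs)[1] != "id")
    stop("covariate table must have 'id' as its first column")
  sid <- as.character(surv$id)
  cid <- as.character(covs$id)
  miss_c <- setdiff(sid, cid)
  miss_s <- setdiff(cid, sid)
  if (length(miss_c))
    stop("samples missing from the covariate file: ",
         paste(utils::head(miss_c, 5), collapse = ", "))
  if (length(miss_s))
    stop("samples missing from the survival file: ",
         paste(utils::head(miss_s, 5), collapse = ", "))
  covs <- covs[match(sid, cid), , drop = FALSE]
  X <- as.matrix(covs[, -1, drop = FALSE])
  if (!is.numeric(X))
    stop("covariate columns must all be numeric")
  if (anyNA(X) || anyNA(surv$time) || anyNA(surv$status))
    stop("missing values are not allowed")
  if (!all(surv$status %in% c(0, 1)))
    stop("status must be coded 0/1; recode the input explicitly")
  if (standardize) {
    mu <- colMeans(X)
    s <- apply(X, 2, sd)
    s[s == 0] <- 1
    X <- sweep(sweep(X, 2, mu), 2, s, "/")
  }
  survival_dataset(surv$time, surv$status, X, ids = sid)
}

#' Write a survival dataset to covariate and survival tables
#'
#' Inverse of [load_dataset()] (without standardization); used by the
#' `simulate` command-line subcommand.
#'
#' @param data A [survival_dataset()].
#' @param cov_path,surv_path Output paths (extension picks TSV vs CSV).
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(data, cov_path, surv_path) {
  sep_of <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  write.table(data.frame(id = data$ids, data$X, check.names = FALSE),
              cov_path, sep = sep_of(cov_path), row.names = FALSE,
              quote = FALSE)
  write.table(data.frame(id = data$ids, time = data$time,
                         status = data$status),
              surv_path, sep = sep_of(surv_path), row.names = FALSE,
              quote = FALSE)
  invisible(c(cov_path, surv_path))
}

#' Read per-feature secondary-data dispersions
#'
#' Accepts either a two-column table `feature`, `sigma`, or a full samples x
#' features matrix (first column `id`) whose per-feature standard deviation
#' across samples is computed.
#'
#' @param path TSV/CSV path.
#' @return Named numeric vector of dispersions.
#' @export
read_secondary_dispersion <- function(path) {
  tab <- read_table_auto(path)
  if (all(c("feature", "sigma") %in% names(tab)))
    return(setNames(as.numeric(tab$sigma), as.character(tab$feature)))
  if (names(tab)[1] != "id")
    stop("secondary file must have columns feature/sigma or an 'id' matrix")
  M <- as.matrix(tab[, -1, drop = FALSE])
  apply(M, 2, sd)
}

#' Keep the features with the highest variance
#'
#' @param X Covariate matrix.
#' @param n_keep Number of features to keep (ties broken by lower column
#'   index).
#' @return `list(X =, kept =, variance_fraction =)`: the reduced matrix, the
#'   kept column indices (in original order) and the fraction of total
#'   variance they carry.
#' @export
select_top_variance <- function(X, n_keep) {
  X <- as.matrix(X)
  stopifnot(n_keep >= 1, n_keep <= ncol(X))
  v <- apply(X, 2, var)
  kept <- sort(order(-v, seq_along(v))[seq_len(n_keep)])
  list(X = X[, kept, drop = FALSE], kept = kept,
       variance_fraction = sum(v[kept]) / sum(v))
}

#' Seeded train/test split
#'
#' @param data A [survival_dataset()].
#' @param ratio Training fraction; the default `2/3` reproduces a 2:1
#'   split (140/70 at n = 210).
#' @param seed Optional seed.
#' @return `list(train =, test =)` of disjoint [survival_dataset()]s
#'   covering all samples, with `ceiling(n * ratio)` training subjects.
#' @export
train_test_split <- function(data, ratio = 2 / 3, seed = NULL) {
  stopifnot(inherits(data, "survival_dataset"), ratio > 0, ratio < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(data$time)
  n_train <- ceiling(n * ratio)
  idx <- sample(n, n_train)
  list(train = dataset_subset(data, sort(idx)),
       test = dataset_subset(data, sort(setdiff(seq_len(n), idx))))
}

#' Read a run configuration file
#'
#' YAML key-value file with any of: `n_iter`, `burn_in`, `thin`, `seed`,
#' `adapt_window`, `adapt_target`, `init_scale`, `k`, `c0`, `tau`, `cb`,
#' `prior` (`uniform` / `cnv` / `correct` / `incorrect`),
#' `standardize`, `t_max`, `prediction_mode`, and a `tempering` block
#' (`enabled`, `n_chains`, `base`, `swap_interval`).  Missing keys take the
#' package defaults.
#'
#' @param path YAML file path.
#' @return Named list of configuration values with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(n_iter = 20000L, burn_in = 5000L, thin = 1L, seed = 1L,
                   adapt_window = 100L, adapt_target = 0.35,
                   init_scale = 0.1, k = 20, c0 = 2, tau = 0.0375, cb = 20,
                   prior = "uniform", standardize = TRUE, t_max = 80,
                   prediction_mode = "plugin",
                   tempering = list(enabled = FALSE, n_chains = 6L,
                                    base = 1.5, swap_interval = 10L))
  merged <- utils::modifyList(defaults, cfg)
  merged$tempering <- utils::modifyList(defaults$tempering,
                                        cfg$tempering %||% list())
  merged
}
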