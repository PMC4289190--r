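# The screening pipeline: per-defect binary models on balanced samples,
# randomized 2/3-1/3 cross-validation for hyperparameter tuning, the
# two-tier classifier (three-class Chorion/Dead/Others gate, then binary
# defect models on images gated as Others), and the carry-over-corrected
# per-defect confusion matrices over the full test set.

#' The 11-term phenotype vocabulary
#'
#' "Dead" and "Chorion" are exclusive of all other terms; "Up Curved
#' Tail/Fish" holds iff "Up Curved Tail" or "Up Curved Fish" holds (it is
#' nevertheless trained as its own binary model, matching how the defect is
#' scored).
#'
#' @return A character vector of the 11 phenotype terms.
#' @export
phenotype_vocabulary <- function() {
  c("Normal", "Dead", "Chorion", "Down Curved Tail", "Hemostasis",
    "Necrosed Yolk Sac", "Edema", "Short Tail", "Up Curved Tail",
    "Up Curved Fish", "Up Curved Tail/Fish")
}

# terms that pass the gate (everything except the two exclusive classes)
other_defects <- function() setdiff(phenotype_vocabulary(), c("Dead", "Chorion"))

#' Parse / format ";"-separated label sets
#'
#' Manifests store the multi-label assignment of an image as a single
#' `;`-separated string.
#'
#' @param x character vector of `;`-separated label strings.
#' @return `parse_labels`: a list of character vectors; `format_labels`
#'   (list input): a character vector.
#' @export
parse_labels <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), trimws)
}

#' @rdname parse_labels
#' @param sets list of character vectors.
#' @export
format_labels <- function(sets) {
  vapply(sets, paste, character(1), collapse = ";")
}

# enforce the vocabulary invariants on a list of label sets
assert_label_sets <- function(sets) {
  vocab <- phenotype_vocabulary()
  for (s in sets) {
    if (length(s) < 1) zs_stop("every image needs >= 1 label", "zs_data_error")
    bad <- setdiff(s, vocab)
    if (length(bad)) {
      zs_stop(paste0("unknown phenotype term(s): ", paste(bad, collapse = ", ")),
              "zs_parameter_error")
    }
    if (any(s %in% c("Dead", "Chorion")) && length(s) > 1) {
      zs_stop("'Dead' and 'Chorion' exclude all other terms", "zs_data_error")
    }
  }
  invisible(sets)
}

#' Read / write a dataset manifest
#'
#' The manifest CSV maps image files to label sets and (optionally)
#' compound/concentration metadata, with columns `filename`,
#' `labels` (`;`-separated), `session`, `split` and, for toxicology runs,
#' `compound` and `concentration`.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("filename", "labels") %in% names(m))) {
    zs_stop("manifest needs at least 'filename' and 'labels' columns",
            "zs_data_error")
  }
  assert_label_sets(parse_labels(m$labels))
  m
}

#' @rdname read_manifest
#' @param manifest data frame to write.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Build a binary one-vs-rest task for one defect
#'
#' Positives are the images whose label set contains the defect, negatives
#' all other images; with `balance = TRUE` the majority class is randomly
#' undersampled (seeded) to the minority size.
#'
#' @param manifest manifest data frame (column `labels`).
#' @param defect a term of [phenotype_vocabulary()].
#' @param balance undersample the majority class?
#' @param seed seed for the undersampling draw.
#' @return The manifest rows of the task with an added factor column
#'   `y` (levels `NO`, `YES`).
#' @export
make_binary_task <- function(manifest, defect, balance = TRUE, seed = 1L) {
  if (!defect %in% phenotype_vocabulary()) {
    zs_stop(paste0("unknown defect: ", defect), "zs_parameter_error")
  }
  sets <- parse_labels(manifest$labels)
  pos <- vapply(sets, function(s) defect %in% s, logical(1))
  if (!any(pos) || all(pos)) {
    zs_stop(paste0("task for '", defect, "' needs >= 1 positive and >= 1 negative"),
            "zs_task_error")
  }
  ip <- which(pos)
  im <- which(!pos)
  if (balance) {
    k <- min(length(ip), length(im))
    if (length(ip) > k) ip <- with_seed(seed, sort(sample(ip, k)))
    if (length(im) > k) im <- with_seed(seed, sort(sample(im, k)))
  }
  keep <- sort(c(ip, im))
  out <- manifest[keep, , drop = FALSE]
  out$y <- factor(ifelse(pos[keep], "YES", "NO"), levels = c("NO", "YES"))
  out
}

#' Hyperparameter grid for tuning
#'
#' @param modes classification modes to try.
#' @param size_ranges list of `c(min_frac, max_frac)` subwindow size ranges.
#' @param test_kinds node-test families to try.
#' @return A data frame, one grid point per row, in the order given (ties
#'   in tuning are resolved toward earlier rows).
#' @export
tuning_grid <- function(modes = c("C", "BAGS"),
                        size_ranges = list(c(0.25, 0.75), c(0.5, 0.9)),
                        test_kinds = c("SIMPLETHRES", "DIFFNEIGHBOR")) {
  if (!length(modes) || !length(size_ranges) || !length(test_kinds)) {
    zs_stop("tuning grid must be non-empty", "zs_parameter_error")
  }
  g <- expand.grid(test_kind = test_kinds,
                   size_range = seq_along(size_ranges),
                   mode = modes, stringsAsFactors = FALSE)
  data.frame(mode = g$mode,
             min_frac = vapply(size_ranges[g$size_range], `[`, numeric(1), 1),
             max_frac = vapply(size_ranges[g$size_range], `[`, numeric(1), 2),
             test_kind = g$test_kind, stringsAsFactors = FALSE)
}

#' Tune classifier hyperparameters by randomized cross-validation
#'
#' For every grid point, the labeled images are split `n_runs` times at
#' random into 2/3 training and 1/3 evaluation (stratified by class; the
#' same seeded splits are reused across grid points), a classifier is
#' trained on each 2/3 and its accuracy measured on the held-out 1/3; the
#' grid point with the best mean accuracy wins (ties go to the earlier grid
#' row).
#'
#' @param images list of image arrays.
#' @param labels one class label per image.
#' @param grid a [tuning_grid()] data frame.
#' @param n_runs number of randomized splits per grid point (the usual
#'   range is 5-75; default 25).
#' @param train_frac training fraction of each split.
#' @param n_subwindows,n_trees,n_tests fixed ensemble settings during
#'   tuning.
#' @param seed integer seed; identical seeds reproduce the selection.
#' @return A list with `best` (row of `grid`), `cv_rate` (its mean
#'   accuracy) and `rates` (mean accuracy per grid point).
#' @export
tune_classifier <- function(images, labels, grid = tuning_grid(),
                            n_runs = 25, train_frac = 2 / 3,
                            n_subwindows = 100, n_trees = 10, n_tests = 28,
                            seed = 1L) {
  if (nrow(grid) == 0) zs_stop("tuning grid is empty", "zs_parameter_error")
  if (!(train_frac > 0 && train_frac < 1)) {
    zs_stop("train_frac must lie in (0, 1)", "zs_parameter_error")
  }
  y <- factor(labels)
  n <- length(images)
  ids <- names(images) %||% as.character(seq_len(n))
  names(images) <- ids

  # the same randomized splits for every grid point (paired comparison)
  splits <- lapply(seq_len(n_runs), function(run) {
    with_seed(derive_seed(seed, paste0("split", run)), {
      tr <- unlist(lapply(split(seq_len(n), y), function(idx) {
        k <- max(1L, round(train_frac * length(idx)))
        if (length(idx) == 1) idx else sample(idx, k)
      }), use.names = FALSE)
      sort(tr)
    })
  })

  rates <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    smp <- sampler_params(n_subwindows = n_subwindows,
                          min_frac = grid$min_frac[g],
                          max_frac = grid$max_frac[g])
    accs <- vapply(seq_len(n_runs), function(run) {
      tr <- splits[[run]]
      te <- setdiff(seq_len(n), tr)
      fit <- larva_classifier(images[tr], y[tr], mode = grid$mode[g],
                              sampler = smp, n_trees = n_trees,
                              n_tests = n_tests,
                              test_kind = grid$test_kind[g],
                              seed = derive_seed(seed, c("fit", g, run)))
      mean(as.character(predict(fit, images[te])) == as.character(y[te]))
    }, numeric(1))
    rates[g] <- mean(accs)
  }
  best <- which.max(rates) # ties: first grid row
  list(best = grid[best, , drop = FALSE], cv_rate = rates[best],
       rates = rates)
}

# gate relabeling: Dead / Chorion / Others
gate_class <- function(sets) {
  vapply(sets, function(s) {
    if ("Dead" %in% s) "Dead" else if ("Chorion" %in% s) "Chorion" else "Others"
  }, character(1))
}

#' Train the three-class Chorion/Dead/Others gate
#'
#' Every image is relabeled to one of the three mutually exclusive gate
#' classes ("Others" covers normal larvae and every non-exclusive defect)
#' and a single multiclass model is trained.
#'
#' @param images list of image arrays.
#' @param manifest manifest data frame for the same images.
#' @param ... passed to [larva_classifier()].
#' @return A `larva_classifier` over `Chorion`, `Dead`, `Others`.
#' @export
train_three_class <- function(images, manifest, ...) {
  g <- gate_class(parse_labels(manifest$labels))
  if (length(unique(g)) < 3) {
    zs_stop("gate training needs Chorion, Dead and Others images",
            "zs_training_error")
  }
  larva_classifier(images, factor(g, levels = c("Chorion", "Dead", "Others")),
                   ...)
}

#' Train the full two-tier classifier
#'
#' Tier one is the three-class gate trained on the whole learning set; tier
#' two is one balanced binary model per remaining vocabulary term
#' (including "Normal", trained directly rather than as the complement of
#' the other calls, and "Up Curved Tail/Fish" as its own model), fitted
#' after removing all Dead and Chorion images.
#'
#' @param images named list of image arrays.
#' @param manifest manifest data frame (`filename`, `labels`).
#' @param mode,sampler,n_trees,n_tests,test_kind,seed shared model settings
#'   (see [larva_classifier()]).
#' @param balance undersample the majority class of each binary task?
#' @return An object of class `two_tier_model`.
#' @export
train_two_tier <- function(images, manifest, mode = "C",
                           sampler = sampler_params(), n_trees = 10,
                           n_tests = 28, test_kind = "SIMPLETHRES",
                           balance = TRUE, seed = 1L) {
  stopifnot(length(images) == nrow(manifest))
  names(images) <- manifest$filename
  gate <- train_three_class(images, manifest, mode = mode, sampler = sampler,
                            n_trees = n_trees, n_tests = n_tests,
                            test_kind = test_kind,
                            seed = derive_seed(seed, "gate"))
  sets <- parse_labels(manifest$labels)
  keep <- !vapply(sets, function(s) any(c("Dead", "Chorion") %in% s),
                  logical(1))
  sub <- manifest[keep, , drop = FALSE]
  sub_images <- images[keep]
  binary_models <- list()
  for (defect in other_defects()) {
    task <- make_binary_task(sub, defect, balance = balance,
                             seed = derive_seed(seed, c("balance", defect)))
    binary_models[[defect]] <-
      larva_classifier(sub_images[match(task$filename, sub$filename)],
                       task$y, mode = mode, sampler = sampler,
                       n_trees = n_trees, n_tests = n_tests,
                       test_kind = test_kind,
                       seed = derive_seed(seed, c("binary", defect)))
  }
  structure(list(gate = gate, binary_models = binary_models,
                 vocabulary = phenotype_vocabulary(), seed = seed),
            class = "two_tier_model")
}

#' @export
print.two_tier_model <- function(x, ...) {
  cat("Two-tier phenotype classifier\n")
  cat(sprintf("  gate: 3-class %s-mode model (Chorion / Dead / Others)\n",
              x$gate$mode))
  cat(sprintf("  binary defect models (%d): %s\n", length(x$binary_models),
              paste(names(x$binary_models), collapse = ", ")))
  invisible(x)
}

#' Predict phenotype label sets with the two-tier classifier
#'
#' Images gated as Dead or Chorion receive that singleton label set and the
#' binary models are never invoked; images gated as Others receive the
#' union of the positive binary calls (an empty union is allowed and
#' flagged unclassified). Gate misrouting is accepted as-is: there is no
#' second-chance routing.
#'
#' @param object a [train_two_tier()] model.
#' @param images named list of image arrays.
#' @param seed base seed for the test-time subwindow draws.
#' @param ... unused.
#' @return A list with `labels` (list of predicted label sets), `gate`
#'   (factor of gate decisions) and `unclassified` (logical).
#' @export
predict.two_tier_model <- function(object, images, seed = NULL, ...) {
  if (length(object$binary_models) < length(other_defects())) {
    zs_stop("a binary model is missing for part of the vocabulary",
            "zs_configuration_error")
  }
  seed <- seed %||% object$seed
  n <- length(images)
  ids <- names(images) %||% as.character(seq_len(n))
  names(images) <- ids
  gate <- predict(object$gate, images, seed = seed)
  labels <- vector("list", n)
  others <- which(gate == "Others")
  calls <- matrix(FALSE, n, length(object$binary_models),
                  dimnames = list(ids, names(object$binary_models)))
  if (length(others)) {
    for (defect in names(object$binary_models)) {
      pr <- predict(object$binary_models[[defect]], images[others],
                    seed = seed)
      calls[others, defect] <- pr == "YES"
    }
  }
  for (i in seq_len(n)) {
    labels[[i]] <- if (gate[i] %in% c("Dead", "Chorion")) {
      as.character(gate[i])
    } else {
      names(object$binary_models)[calls[i, ]]
    }
  }
  list(labels = labels, gate = gate,
       unclassified = lengths(labels) == 0)
}

#' Carry-over-corrected per-defect confusion matrices
#'
#' Scores the final two-tier output against the truth over the entire test
#' set: an image wrongly gated out as Dead/Chorion is negative for every
#' other term, so it counts as a false negative for each true defect it
#' carries; an image wrongly gated in is scored by its binary calls. For
#' every term TP + FP + TN + FN equals the test-set size.
#'
#' @param predicted list of predicted label sets (from
#'   [predict.two_tier_model()], `$labels`).
#' @param truth list of true label sets.
#' @param vocabulary terms to score (default the full 11-term vocabulary).
#' @return A data frame with one row per term: `TP`, `FP`, `TN`, `FN`,
#'   `rate_pos`, `rate_neg`, `accuracy`.
#' @export
aggregate_two_tier_confusion <- function(predicted, truth,
                                         vocabulary = phenotype_vocabulary()) {
  if (length(predicted) != length(truth)) {
    zs_stop("predicted and truth must have the same length", "zs_data_error")
  }
  assert_label_sets(truth)
  n <- length(truth)
  out <- data.frame(defect = vocabulary, TP = 0L, FP = 0L, TN = 0L, FN = 0L,
                    stringsAsFactors = FALSE)
  for (k in seq_along(vocabulary)) {
    term <- vocabulary[k]
    p <- vapply(predicted, function(s) term %in% s, logical(1))
    t <- vapply(truth, function(s) term %in% s, logical(1))
    out$TP[k] <- sum(p & t)
    out$FP[k] <- sum(p & !t)
    out$TN[k] <- sum(!p & !t)
    out$FN[k] <- sum(!p & t)
  }
  out$rate_pos <- ifelse(out$TP + out$FN > 0, out$TP / (out$TP + out$FN), NA)
  out$rate_neg <- ifelse(out$TN + out$FP > 0, out$TN / (out$TN + out$FP), NA)
  out$accuracy <- (out$TP + out$TN) / n
  out
}
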