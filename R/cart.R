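# Minimal CART (classification and regression trees) used as the base
# learner for the decision-tree, random-forest and gradient-boosting
# classifiers. Splits minimise Gini impurity (classification on y in {0,1})
# or squared error (regression); importance is mean decrease in impurity.

cart_fit <- function(x, y, type = c("class", "reg"), max_depth = Inf,
                     min_leaf = 1L, mtry = NULL, min_gain = 1e-10) {
  type <- match.arg(type)
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (is.null(mtry)) mtry <- p
  mtry <- max(1L, min(p, as.integer(mtry)))
  nodes <- list()
  importance <- stats::setNames(numeric(p), colnames(x))

  impurity <- function(idx) {
    yy <- y[idx]
    if (type == "class") {
      pr <- mean(yy); 2 * pr * (1 - pr) * length(idx)   # n * gini
    } else sum((yy - mean(yy))^2)                        # SSE
  }

  best_split <- function(idx, feats) {
    n_i <- length(idx)
    parent <- impurity(idx)
    best <- NULL
    for (f in feats) {
      xv <- x[idx, f]
      ord <- order(xv)
      xs <- xv[ord]; ys <- y[idx][ord]
      cs <- cumsum(ys)
      k <- seq_len(n_i - 1L)
      valid <- xs[k] < xs[k + 1L] & k >= min_leaf & (n_i - k) >= min_leaf
      if (!any(valid)) next
      if (type == "class") {
        pl <- cs[k] / k
        pr <- (cs[n_i] - cs[k]) / (n_i - k)
        child <- 2 * (k * pl * (1 - pl) + (n_i - k) * pr * (1 - pr))
      } else {
        cs2 <- cumsum(ys^2)
        sse_l <- cs2[k] - cs[k]^2 / k
        sse_r <- (cs2[n_i] - cs2[k]) - (cs[n_i] - cs[k])^2 / (n_i - k)
        child <- sse_l + sse_r
      }
      child[!valid] <- Inf
      kbest <- which.min(child)
      gain <- parent - child[kbest]
      if (is.null(best) || gain > best$gain)
        best <- list(gain = gain, var = f,
                     val = (xs[kbest] + xs[kbest + 1L]) / 2)
    }
    best
  }

  build <- function(idx, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list()  # reserve slot
    pred <- mean(y[idx])
    leaf <- list(id = id, leaf = TRUE, pred = pred, n = length(idx),
                 var = NA_integer_, val = NA_real_, left = NA_integer_,
                 right = NA_integer_)
    if (depth >= max_depth || length(idx) < 2L * min_leaf ||
        length(unique(y[idx])) == 1L) {
      nodes[[id]] <<- leaf
      return(id)
    }
    feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
    sp <- best_split(idx, feats)
    if (is.null(sp) || sp$gain <= min_gain) {
      nodes[[id]] <<- leaf
      return(id)
    }
    importance[sp$var] <<- importance[sp$var] + sp$gain / n
    go_left <- x[idx, sp$var] <= sp$val
    l <- build(idx[go_left], depth + 1L)
    r <- build(idx[!go_left], depth + 1L)
    nodes[[id]] <<- list(id = id, leaf = FALSE, pred = pred, n = length(idx),
                         var = sp$var, val = sp$val, left = l, right = r)
    id
  }

  build(seq_len(n), 0L)
  structure(list(nodes = nodes, importance = importance, type = type,
                 p = p), class = "cart_tree")
}

# type "response": leaf prediction; type "node": leaf node id
cart_predict <- function(tree, x, type = c("response", "node")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  out <- numeric(nrow(x))
  recurse <- function(id, idx) {
    nd <- tree$nodes[[id]]
    if (nd$leaf) {
      out[idx] <<- if (type == "response") nd$pred else nd$id
      return(invisible(NULL))
    }
    go_left <- x[idx, nd$var] <= nd$val
    if (any(go_left)) recurse(nd$left, idx[go_left])
    if (any(!go_left)) recurse(nd$right, idx[!go_left])
  }
  if (nrow(x)) recurse(1L, seq_len(nrow(x)))
  out
}

cart_set_leaf_values <- function(tree, values) {
  for (id in as.integer(names(values)))
    tree$nodes[[id]]$pred <- values[[as.character(id)]]
  tree
}

# ---- random forest ----------------------------------------------------------

rf_fit <- function(x, y, n_trees = 100L, mtry = NULL, max_depth = Inf,
                   min_leaf = 1L) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  trees <- vector("list", n_trees)
  imp <- stats::setNames(numeric(p), colnames(x))
  for (b in seq_len(n_trees)) {
    idx <- sample.int(nrow(x), replace = TRUE)
    trees[[b]] <- cart_fit(x[idx, , drop = FALSE], y[idx], "class",
                           max_depth = max_depth, min_leaf = min_leaf,
                           mtry = mtry)
    imp <- imp + trees[[b]]$importance
  }
  structure(list(trees = trees, importance = imp / n_trees),
            class = "rf_model")
}

rf_predict <- function(model, x) {
  pr <- vapply(model$trees, cart_predict, numeric(nrow(as.matrix(x))),
               x = as.matrix(x))
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
  rowMeans(pr)
}

# ---- gradient-boosted trees (logistic loss, Newton leaf steps) -------------

gbt_fit <- function(x, y, n_rounds = 100L, depth = 3L, learning_rate = 0.1,
                    min_leaf = 1L, lambda = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  f0 <- log(p0 / (1 - p0))
  fx <- rep(f0, n)
  trees <- vector("list", n_rounds)
  imp <- stats::setNames(numeric(ncol(x)), colnames(x))
  for (m in seq_len(n_rounds)) {
    pr <- stats::plogis(fx)
    g <- y - pr
    h <- pmax(pr * (1 - pr), 1e-6)
    tree <- cart_fit(x, g, "reg", max_depth = depth, min_leaf = min_leaf)
    leaf_of <- cart_predict(tree, x, type = "node")
    gamma <- tapply(g, leaf_of, sum) / (tapply(h, leaf_of, sum) + lambda)
    tree <- cart_set_leaf_values(tree, as.list(gamma))
    fx <- fx + learning_rate * cart_predict(tree, x)
    trees[[m]] <- tree
    imp <- imp + tree$importance
  }
  structure(list(f0 = f0, trees = trees, learning_rate = learning_rate,
                 importance = imp), class = "gbt_model")
}

gbt_predict <- function(model, x) {
  x <- as.matrix(x)
  fx <- rep(model$f0, nrow(x))
  for (tree in model$trees)
    fx <- fx + model$learning_rate * cart_predict(tree, x)
  stats::plogis(fx)
}

# ---- RBF-kernel SVM on a 95%-variance PCA projection -----------------------

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

svm_fit <- function(x, y, cost = 1, gamma = NULL, var_retained = 0.95) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2) stop("single-class input")
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  varfrac <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  ncomp <- max(1L, which(varfrac >= var_retained)[1])
  z <- pca$x[, seq_len(ncomp), drop = FALSE]
  if (is.null(gamma)) gamma <- 1 / ncol(z)
  yy <- ifelse(y > 0.5, 1, -1)
  n <- nrow(z)
  K <- rbf_kernel(z, z, gamma)
  D <- (yy %o% yy) * K + diag(1e-7, n)
  A <- cbind(yy, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(D, rep(1, n), A, b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), cost)
  sv <- alpha > 1e-8
  margin <- sv & alpha < cost - 1e-8
  use <- if (any(margin)) margin else sv
  fb <- K[use, , drop = FALSE] %*% (alpha * yy)
  b <- mean(yy[use] - fb)
  structure(list(pca_center = pca$center,
                 rotation = pca$rotation[, seq_len(ncomp), drop = FALSE],
                 gamma = gamma, alpha = alpha, yy = yy, sv_z = z, b = b),
            class = "svm_model")
}

svm_decision <- function(model, x) {
  z <- sweep(as.matrix(x), 2, model$pca_center) %*% model$rotation
  Kn <- rbf_kernel(z, model$sv_z, model$gamma)
  as.vector(Kn %*% (model$alpha * model$yy) + model$b)
}

svm_predict <- function(model, x) stats::plogis(svm_decision(model, x))
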