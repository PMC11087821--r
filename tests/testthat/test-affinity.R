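test_that("gene matrix SVD is truncated with the stated orientation", {
  g <- GeneScoreMatrix(namedMatrix(diag(c(3, 2, 1)), 3, "gene", "ph"))
  dec <- decomposeGeneMatrix(g, 2)
  expect_equal(dec@d, c(3, 2), tolerance = 1e-12)
  expect_identical(rownames(dec@u), paste0("gene", 1:3))
  expect_identical(rownames(dec@v), paste0("ph", 1:3))
  # full rank reconstructs exactly
  set.seed(1)
  g2 <- GeneScoreMatrix(namedMatrix(rnorm(50), 10, "gene", "ph"))
  dec2 <- decomposeGeneMatrix(g2, 5)
  expect_lt(max(abs(dec2@u %*% (dec2@d * t(dec2@v)) - values(g2))), 1e-8)
  # Eckart-Young optimum at r = 5 on a 20 x 10 matrix
  g3 <- GeneScoreMatrix(namedMatrix(rnorm(200), 20, "gene", "ph"))
  dec3 <- decomposeGeneMatrix(g3, 5)
  err <- sum((values(g3) - dec3@u %*% (dec3@d * t(dec3@v)))^2)
  expect_equal(err, sum(svd(values(g3))$d[-(1:5)]^2), tolerance = 1e-10)
  # rank beyond numerical rank truncates with a warning
  g4 <- GeneScoreMatrix(namedMatrix(as.vector(tcrossprod(rnorm(6), rnorm(4))),
                                    6, "gene", "ph"))
  expect_warning(dec4 <- decomposeGeneMatrix(g4, 3), "numerical rank")
  expect_equal(length(dec4@d), 1L)
})

test_that("the Kronecker design satisfies the vec identity", {
  # hand-enumerated 2 x 2 case at r_D = r_P = 1
  f <- matrix(c(2, -1), 2, dimnames = list(c("d1", "d2"), NULL))
  vp <- matrix(c(3, 4), 2)
  x <- buildDesign(f, vp)
  expect_equal(as.vector(x), c(6, -3, 8, -4))  # drug index fastest
  # (B %x% A) vec(X) = vec(A X B') on random triples
  set.seed(2)
  for (rep in 1:100) {
    a <- matrix(rnorm(8), 4, 2)
    xw <- matrix(rnorm(6), 2, 3)
    b <- matrix(rnorm(15), 5, 3)
    lhs <- buildDesign(a, b) %*% as.vector(xw)
    expect_equal(as.vector(lhs), as.vector(a %*% xw %*% t(b)),
                 tolerance = 1e-12)
    # and against base kronecker as an independent construction
    expect_equal(buildDesign(a, b), kronecker(b, a), tolerance = 1e-14,
                 ignore_attr = TRUE)
  }
  # subset rows keep the given pair order
  sub <- cbind(c(2, 1), c(3, 1))
  xs <- buildDesign(a, b, pairSubset = sub)
  expect_equal(xs[1, ], kronecker(b, a)[(3 - 1) * 4 + 2, ], ignore_attr = TRUE)
})

test_that("factorized fitting equals explicit expanded-feature regression", {
  # 10 drugs x 6 phenotypes at full ranks: identical coefficients and loss
  set.seed(3)
  f <- namedMatrix(rnorm(30), 10, "drug", "f")
  gd <- decomposeGeneMatrix(
    GeneScoreMatrix(namedMatrix(rnorm(8 * 6), 8, "gene", "ph")), 3)
  y <- AssociationMatrix(namedMatrix(rbinom(60, 1, 0.35), 10, "drug", "ph"))
  fit <- fitAffinity(f, gd, y, l1Strength = 0.02)
  xExplicit <- kronecker(gd@v, f)  # independent design construction
  ref <- glmnet::glmnet(xExplicit, as.vector(values(y)), family = "binomial",
                        alpha = 1, lambda = 0.02, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
  expect_equal(as.vector(fit@wdp), as.numeric(ref$beta[, 1]),
               tolerance = 1e-6)
  expect_equal(fit@intercept, as.numeric(ref$a0[1]), tolerance = 1e-6)
  # identical penalised log-loss
  loss <- function(w, b) {
    eta <- b + f %*% matrix(w, 3, 3) %*% t(gd@v)
    yv <- values(y)
    -mean(yv * eta - log(1 + exp(eta))) + 0.02 * sum(abs(w))
  }
  expect_equal(loss(as.vector(fit@wdp), fit@intercept),
               loss(as.numeric(ref$beta[, 1]), as.numeric(ref$a0[1])),
               tolerance = 1e-9)
})

test_that("predictions equal the dense bilinear oracle and behave at limits", {
  fx <- smallFit()
  model <- fx$model
  p <- predictAssociation(model)
  oracle <- plogis(model@intercept +
                     model@drugFactors %*% model@wdp %*% t(model@geneDecomp@v))
  expect_equal(unname(p), unname(oracle), tolerance = 1e-12)
  expect_true(all(p > 0 & p < 1))
  # W_DP = 0 -> constant base-rate probability
  z <- model
  z@wdp[] <- 0
  expect_equal(unname(unique(as.vector(predictAssociation(z)))),
               plogis(model@intercept), tolerance = 1e-12)
  # a huge penalty drives W_DP to zero
  big <- fitAffinity(model@drugFactors, model@geneDecomp, fx$sim$assoc,
                     l1Strength = 100)
  expect_true(all(big@wdp == 0))
  expect_equal(unname(as.vector(predictAssociation(big)))[1],
               mean(values(fx$sim$assoc)), tolerance = 1e-6)
})

test_that("probabilities are invariant to an orthogonal phenotype-factor rotation", {
  fx <- smallFit()
  model <- fx$model
  r <- ncol(model@wdp)
  set.seed(4)
  q <- qr.Q(qr(matrix(rnorm(r * r), r)))
  rot <- model
  rot@geneDecomp <- model@geneDecomp  # rotate (V_P, W_DP) consistently
  rot@geneDecomp@v <- model@geneDecomp@v %*% q
  rot@wdp <- model@wdp %*% q
  # bypass validity (rotated v stays orthonormal, d no longer matches svd order)
  expect_equal(plogis(rot@intercept + rot@drugFactors %*% rot@wdp %*%
                        t(rot@geneDecomp@v)),
               predictAssociation(model), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("monotone factor increase with nonnegative weights raises probabilities", {
  set.seed(5)
  f <- namedMatrix(rnorm(10), 5, "drug", "f")
  # nonnegative orthonormal phenotype factors (disjoint support), so
  # W_DP %*% t(V_P) is entrywise nonnegative for nonnegative W_DP
  vp <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)) / sqrt(2)
  gd <- new("Decomposition", u = qr.Q(qr(matrix(rnorm(12), 6)))[, 1:2],
            d = c(2, 1), v = vp, lambda = 0)
  model <- new("AffinityModel", wdp = matrix(abs(rnorm(4)), 2), intercept = 0,
               drugFactors = f, geneDecomp = gd, l1Strength = 1,
               polarity = "side_effects", phenotypeIds = paste0("ph", 1:4),
               usedIntercept = TRUE)
  p0 <- predictAssociation(model)
  f2 <- f; f2[, 1] <- f2[, 1] + 1
  p1 <- predictAssociation(model, f2)
  expect_true(all(p1 - p0 >= -1e-12))
  expect_true(any(p1 > p0))
})

test_that("duplicating every pair leaves the fit unchanged", {
  set.seed(6)
  f <- namedMatrix(rnorm(16), 8, "drug", "f")
  gd <- decomposeGeneMatrix(
    GeneScoreMatrix(namedMatrix(rnorm(24), 6, "gene", "ph")), 2)
  y <- namedMatrix(rbinom(32, 1, 0.3), 8, "drug", "ph")
  fit1 <- fitAffinity(f, gd, AssociationMatrix(y), l1Strength = 0.05)
  x <- buildDesign(f, gd@v)
  yv <- as.vector(y)
  dup <- glmnet::glmnet(rbind(x, x), c(yv, yv), family = "binomial", alpha = 1,
                        lambda = 0.05, standardize = FALSE, thresh = 1e-10,
                        maxit = 1e6)
  expect_equal(as.vector(fit1@wdp), as.numeric(dup$beta[, 1]),
               tolerance = 1e-6)
})

test_that("degenerate or misaligned training input is rejected", {
  fx <- smallFit()
  yAll0 <- values(fx$sim$assoc); yAll0[] <- 0
  expect_error(fitAffinity(drugFactors(fx$dec), fx$gd,
                           AssociationMatrix(yAll0), l1Strength = 0.01),
               "degenerate")
  shuffled <- drugFactors(fx$dec)
  rownames(shuffled) <- rev(rownames(shuffled))
  expect_error(fitAffinity(shuffled, fx$gd, fx$sim$assoc, l1Strength = 0.01),
               "order")
  expect_error(predictAssociation(fx$model,
                                  matrix(0, 2, ncol(fx$model@wdp) + 1)),
               "r_D")
})

test_that("planted sparse interactions are recovered in sign at weak penalty", {
  # Y ~ Bernoulli(sigmoid(F W* V')) with sparse W*: refit recovers signs
  set.seed(7)
  n <- 120; m <- 40; r <- 4
  f <- namedMatrix(rnorm(n * r), n, "drug", "f")
  vp <- qr.Q(qr(matrix(rnorm(m * r), m)))
  wStar <- matrix(0, r, r)
  nz <- sample(r * r, 6)
  wStar[nz] <- sample(c(-1, 1), 6, replace = TRUE)
  eta <- f %*% wStar %*% t(vp)
  eta <- eta * 2 / sd(eta)
  y <- namedMatrix(rbinom(n * m, 1, plogis(eta)), n, "drug", "ph")
  gd <- new("Decomposition", u = qr.Q(qr(matrix(rnorm(60 * r), 60))),
            d = rep(1, r), v = vp, lambda = 0)
  fit <- fitAffinity(f, gd, AssociationMatrix(y), l1Strength = 0.001)
  fitted <- fit@wdp[nz]
  expect_gt(mean(sign(fitted[fitted != 0]) == sign(wStar[nz][fitted != 0])), 0.8)
})

test_that("drug-held-out tuning prefers the true ranks and returns single points", {
  fx <- smallFit()
  one <- tuneAffinity(fx$dec, fx$sim$genes, fx$sim$assoc,
                      rdGrid = 4, rpGrid = 4, l1Grid = 0.01, nFolds = 5, seed = 1)
  expect_equal(one$rD, 4); expect_equal(one$rP, 4)
  expect_equal(one$l1Strength, 0.01)
  tuned <- tuneAffinity(fx$dec, fx$sim$genes, fx$sim$assoc,
                        rdGrid = c(1, 4), rpGrid = c(1, 4), l1Grid = 0.01,
                        nFolds = 5, seed = 1)
  tab <- tuned$aucTable
  expect_gt(tab$meanAuc[tab$rD == 4 & tab$rP == 4],
            tab$meanAuc[tab$rD == 1 & tab$rP == 1])
})

test_that("tuning on shuffled labels finds no signal", {
  fx <- defaultSim()
  yv <- values(fx$sim$assoc)
  set.seed(8)
  yn <- matrix(sample(as.vector(yv)), nrow(yv), dimnames = dimnames(yv))
  tuned <- tuneAffinity(fx$dec, fx$sim$genes, AssociationMatrix(yn),
                        rdGrid = 4, rpGrid = 4, l1Grid = 0.01, nFolds = 5,
                        seed = 1)
  expect_lt(abs(max(tuned$aucTable$meanAuc) - 0.5), 0.05)
})
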