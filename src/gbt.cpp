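// Multiclass gradient-boosted CARTs (second-order, exact greedy splits).
//
// One binary-outcome ensemble per class, trained additively on the softmax
// objective: per round, per class, a regression tree is fitted to the
// first/second-order gradients and added with learning rate eta.  Supports
// the regularisation surface of mainstream boosting libraries: gamma
// (min split gain), lambda (L2 on leaf weights), min_child_weight (min
// hessian per child), max_delta_step (cap on absolute leaf weight),
// row subsampling and column subsampling per tree / per level.  Early
// stopping monitors validation multiclass log-loss.
//
// Randomness comes from a private xorshift64* stream seeded from R, so
// training is bit-reproducible across platforms independently of R's RNG.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : UINT64_C(0x9E3779B97F4A7C15)) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * UINT64_C(2685821657736338717);
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  // Fisher-Yates draw of k of n indices (first k of a partial shuffle)
  std::vector<int> sample(int n, int k) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = 0; i < k; ++i) {
      int j = i + (int)(unif() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(idx[i], idx[j]);
    }
    idx.resize(k);
    return idx;
  }
};

struct Node {
  int feat = -1;         // -1 => leaf
  double thr = 0.0;
  double leaf = 0.0;
  int left = -1, right = -1;
};

struct Params {
  double eta, gamma, lambda, min_child_weight, subsample;
  double colsample_bytree, colsample_bylevel, max_delta_step;
  int max_depth;
};

struct Tree {
  std::vector<Node> nodes;

  double predict_row(const double* x, int n, int d) const {
    (void)d;
    int cur = 0;
    while (nodes[cur].feat >= 0) {
      double v = x[(size_t)nodes[cur].feat * n];
      cur = (v < nodes[cur].thr) ? nodes[cur].left : nodes[cur].right;
    }
    return nodes[cur].leaf;
  }
};

double leaf_weight(double G, double H, const Params& p) {
  double w = -G / (H + p.lambda);
  if (p.max_delta_step > 0.0) {
    if (w > p.max_delta_step) w = p.max_delta_step;
    if (w < -p.max_delta_step) w = -p.max_delta_step;
  }
  return w;
}

// Recursive exact-greedy construction on the rows in `rows`.
int build_node(Tree& tree, const NumericMatrix& X,
               const std::vector<double>& g, const std::vector<double>& h,
               std::vector<int>& rows, int depth, const Params& p,
               const std::vector<int>& tree_cols, Rng& rng) {
  double G = 0.0, H = 0.0;
  for (int i : rows) { G += g[i]; H += h[i]; }

  int id = (int)tree.nodes.size();
  tree.nodes.push_back(Node());
  tree.nodes[id].leaf = leaf_weight(G, H, p);
  if (depth >= p.max_depth || rows.size() < 2) return id;

  // column subsample per level
  std::vector<int> cols = tree_cols;
  if (p.colsample_bylevel < 1.0) {
    int k = std::max(1, (int)std::floor(p.colsample_bylevel * tree_cols.size()));
    std::vector<int> pick = rng.sample((int)tree_cols.size(), k);
    cols.clear();
    for (int j : pick) cols.push_back(tree_cols[j]);
    std::sort(cols.begin(), cols.end());
  }

  const double parent_score = G * G / (H + p.lambda);
  double best_gain = 0.0, best_thr = 0.0;
  int best_feat = -1;
  const int n = X.nrow();

  std::vector<std::pair<double, int> > vals;
  vals.reserve(rows.size());
  for (int j : cols) {
    vals.clear();
    const double* col = &X(0, j);
    for (int i : rows) vals.push_back(std::make_pair(col[i], i));
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    double GL = 0.0, HL = 0.0;
    for (size_t r = 0; r + 1 < vals.size(); ++r) {
      GL += g[vals[r].second];
      HL += h[vals[r].second];
      if (vals[r].first == vals[r + 1].first) continue;
      double GR = G - GL, HR = H - HL;
      if (HL < p.min_child_weight || HR < p.min_child_weight) continue;
      double gain = 0.5 * (GL * GL / (HL + p.lambda) +
                           GR * GR / (HR + p.lambda) - parent_score) - p.gamma;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_feat = j;
        best_thr = 0.5 * (vals[r].first + vals[r + 1].first);
      }
    }
  }
  (void)n;
  if (best_feat < 0) return id;

  std::vector<int> lrows, rrows;
  const double* col = &X(0, best_feat);
  for (int i : rows) {
    if (col[i] < best_thr) lrows.push_back(i); else rrows.push_back(i);
  }
  if (lrows.empty() || rrows.empty()) return id;
  rows.clear(); rows.shrink_to_fit();

  tree.nodes[id].feat = best_feat;
  tree.nodes[id].thr = best_thr;
  int l = build_node(tree, X, g, h, lrows, depth + 1, p, tree_cols, rng);
  int r = build_node(tree, X, g, h, rrows, depth + 1, p, tree_cols, rng);
  tree.nodes[id].left = l;
  tree.nodes[id].right = r;
  return id;
}

void softmax_rows(const std::vector<double>& F, int n, int K,
                  std::vector<double>& P) {
  for (int i = 0; i < n; ++i) {
    double m = F[i];
    for (int k = 1; k < K; ++k) m = std::max(m, F[i + (size_t)k * n]);
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      double e = std::exp(F[i + (size_t)k * n] - m);
      P[i + (size_t)k * n] = e;
      s += e;
    }
    for (int k = 0; k < K; ++k) P[i + (size_t)k * n] /= s;
  }
}

double mlogloss(const std::vector<double>& P, const IntegerVector& y, int n) {
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double pi = P[i + (size_t)y[i] * n];
    ll -= std::log(std::max(pi, 1e-15));
  }
  return ll / n;
}

List tree_to_list(const Tree& t) {
  int m = (int)t.nodes.size();
  IntegerVector feat(m), left(m), right(m);
  NumericVector thr(m), leaf(m);
  for (int i = 0; i < m; ++i) {
    feat[i] = t.nodes[i].feat;  thr[i] = t.nodes[i].thr;
    leaf[i] = t.nodes[i].leaf;  left[i] = t.nodes[i].left;
    right[i] = t.nodes[i].right;
  }
  return List::create(_["feat"] = feat, _["thr"] = thr, _["leaf"] = leaf,
                      _["left"] = left, _["right"] = right);
}

Tree tree_from_list(const List& l) {
  IntegerVector feat = l["feat"], left = l["left"], right = l["right"];
  NumericVector thr = l["thr"], leaf = l["leaf"];
  if (feat.size() == 0 || feat.size() != thr.size() ||
      feat.size() != leaf.size() || feat.size() != left.size() ||
      feat.size() != right.size())
    stop("malformed tree in model bundle");
  Tree t;
  t.nodes.resize(feat.size());
  for (int i = 0; i < feat.size(); ++i) {
    t.nodes[i].feat = feat[i];  t.nodes[i].thr = thr[i];
    t.nodes[i].leaf = leaf[i];  t.nodes[i].left = left[i];
    t.nodes[i].right = right[i];
  }
  return t;
}

}  // namespace

// [[Rcpp::export(name = ".gbt_train")]]
List gbt_train(NumericMatrix X, IntegerVector y, int nclass,
               NumericMatrix Xval, IntegerVector yval, List params,
               int nrounds, int early_stopping_rounds, int seed) {
  const int n = X.nrow(), d = X.ncol(), nv = Xval.nrow();
  Params p;
  p.eta = as<double>(params["eta"]);
  p.gamma = as<double>(params["gamma"]);
  p.lambda = as<double>(params["lambda"]);
  p.min_child_weight = as<double>(params["min_child_weight"]);
  p.subsample = as<double>(params["subsample"]);
  p.colsample_bytree = as<double>(params["colsample_bytree"]);
  p.colsample_bylevel = as<double>(params["colsample_bylevel"]);
  p.max_delta_step = as<double>(params["max_delta_step"]);
  p.max_depth = as<int>(params["max_depth"]);

  Rng rng((uint64_t)(uint32_t)seed * UINT64_C(0x100000001B3) + 1442695040888963407ULL);

  std::vector<double> F((size_t)n * nclass, 0.0), P((size_t)n * nclass);
  std::vector<double> Fv((size_t)nv * nclass, 0.0), Pv((size_t)nv * nclass);
  std::vector<double> g(n), h(n);

  std::vector<std::vector<Tree> > rounds;  // rounds x nclass
  NumericVector val_ll(nrounds, NA_REAL);
  int best_round = -1;
  double best_ll = R_PosInf;

  for (int r = 0; r < nrounds; ++r) {
    softmax_rows(F, n, nclass, P);
    std::vector<Tree> ktrees(nclass);
    for (int k = 0; k < nclass; ++k) {
      for (int i = 0; i < n; ++i) {
        double pik = P[i + (size_t)k * n];
        g[i] = pik - (y[i] == k ? 1.0 : 0.0);
        h[i] = std::max(2.0 * pik * (1.0 - pik), 1e-16);
      }
      std::vector<int> rows;
      if (p.subsample < 1.0) {
        rows.reserve((size_t)(n * p.subsample) + 1);
        for (int i = 0; i < n; ++i)
          if (rng.unif() < p.subsample) rows.push_back(i);
        if (rows.empty()) rows.push_back((int)(rng.unif() * n));
      } else {
        rows.resize(n);
        for (int i = 0; i < n; ++i) rows[i] = i;
      }
      std::vector<int> tree_cols;
      if (p.colsample_bytree < 1.0) {
        int kk = std::max(1, (int)std::floor(p.colsample_bytree * d));
        tree_cols = rng.sample(d, kk);
        std::sort(tree_cols.begin(), tree_cols.end());
      } else {
        tree_cols.resize(d);
        for (int j = 0; j < d; ++j) tree_cols[j] = j;
      }
      Tree t;
      build_node(t, X, g, h, rows, 0, p, tree_cols, rng);
      // fold the learning rate into the stored leaves so that stored trees
      // are self-contained for prediction
      for (size_t ni = 0; ni < t.nodes.size(); ++ni) t.nodes[ni].leaf *= p.eta;
      for (int i = 0; i < n; ++i)
        F[i + (size_t)k * n] += t.predict_row(&X(i, 0), n, d);
      ktrees[k] = t;
    }
    rounds.push_back(ktrees);
    if (nv > 0) {
      for (int k = 0; k < nclass; ++k)
        for (int i = 0; i < nv; ++i)
          Fv[i + (size_t)k * nv] += ktrees[k].predict_row(&Xval(i, 0), nv, d);
      softmax_rows(Fv, nv, nclass, Pv);
      double ll = mlogloss(Pv, yval, nv);
      val_ll[r] = ll;
      if (ll < best_ll - 1e-12) { best_ll = ll; best_round = r; }
      if (early_stopping_rounds > 0 && r - best_round >= early_stopping_rounds)
        break;
    } else {
      best_round = r;
    }
  }

  int used = best_round + 1;
  List out_rounds(used);
  for (int r = 0; r < used; ++r) {
    List kt(nclass);
    for (int k = 0; k < nclass; ++k) kt[k] = tree_to_list(rounds[r][k]);
    out_rounds[r] = kt;
  }
  return List::create(_["rounds"] = out_rounds, _["nclass"] = nclass,
                      _["nfeat"] = d, _["best_round"] = best_round + 1,
                      _["val_logloss"] = val_ll);
}

// [[Rcpp::export(name = ".gbt_predict")]]
NumericMatrix gbt_predict(List model, NumericMatrix X) {
  List rounds = model["rounds"];
  const int K = as<int>(model["nclass"]);
  const int n = X.nrow(), d = X.ncol();
  if (d != as<int>(model["nfeat"]))
    stop("feature dimension mismatch: model expects %d, got %d",
         as<int>(model["nfeat"]), d);
  std::vector<double> F((size_t)n * K, 0.0);
  for (int r = 0; r < rounds.size(); ++r) {
    List kt = rounds[r];
    for (int k = 0; k < K; ++k) {
      Tree t = tree_from_list(kt[k]);
      for (int i = 0; i < n; ++i)
        F[i + (size_t)k * n] += t.predict_row(&X(i, 0), n, d);
    }
  }
  std::vector<double> P((size_t)n * K);
  softmax_rows(F, n, K, P);
  NumericMatrix out(n, K);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < n; ++i) out(i, k) = P[i + (size_t)k * n];
  return out;
}

// [[Rcpp::export(name = ".hash_embed")]]
NumericMatrix hash_embed(List token_lists, int dim) {
  // Signed Bloom-style feature hashing of token multisets: each token is
  // mapped into TWO buckets by independent FNV-1a hashes, each with a
  // pseudo-random sign.  A single hash leaves a non-negligible share of
  // tokens with identical (bucket, sign) signatures at desk-scale dims,
  // which makes distinct tokens genuinely indistinguishable downstream;
  // with two buckets, full-signature collisions are vanishingly rare.
  // Empty token list => zero row.
  const int n = token_lists.size();
  NumericMatrix out(n, dim);
  for (int i = 0; i < n; ++i) {
    CharacterVector toks = token_lists[i];
    for (int t = 0; t < toks.size(); ++t) {
      const char* s = CHAR(STRING_ELT(toks, t));
      uint32_t h1 = 2166136261u;            // FNV offset basis
      uint32_t h2 = 0x811C9DC5u ^ 0x5BD1E995u;  // decorrelated basis
      for (const char* c = s; *c; ++c) {
        h1 ^= (uint8_t)(*c);  h1 *= 16777619u;
        h2 ^= (uint8_t)(*c);  h2 *= 16777619u;  h2 ^= h2 >> 13;
      }
      uint32_t m1 = h1 * 2654435761u;  // Knuth multiplicative mix
      uint32_t m2 = h2 * 2246822519u;
      out(i, (int)(h1 % (uint32_t)dim)) += (m1 >> 31) ? 1.0 : -1.0;
      out(i, (int)(h2 % (uint32_t)dim)) += (m2 >> 31) ? 1.0 : -1.0;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".fnv1a64")]]
CharacterVector fnv1a64(CharacterVector x) {
  // 64-bit FNV-1a as fixed-width hex; used for config fingerprints.
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    const char* s = CHAR(STRING_ELT(x, i));
    uint64_t hsh = UINT64_C(14695981039346656037);
    for (const char* c = s; *c; ++c) {
      hsh ^= (uint8_t)(*c);
      hsh *= UINT64_C(1099511628211);
    }
    char buf[17];
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)hsh);
    out[i] = buf;
  }
  return out;
}
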