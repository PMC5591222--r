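#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Closest point on a triangle (a, b, c) to point p, after Ericson,
// "Real-Time Collision Detection", 5.1.5. Exact (no epsilon tuning):
// classifies p against the Voronoi regions of the triangle's features.
static inline void closest_on_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }

  double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
}

struct Node {
  double lo[3], hi[3];
  int left, right;   // children (node indices) or -1 for leaf
  int begin, end;    // triangle index range [begin, end) when leaf
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<int> tri;          // triangle indices, permuted by the build
  std::vector<double> Vstore;    // owned copies so the tree can be cached
  std::vector<int> Fstore;
  const double *V;               // nv x 3, column-major from R
  const int *F;                  // nf x 3, column-major, 0-based
  int nv, nf;

  void tri_bounds(int t, double *lo, double *hi) const {
    for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
    for (int j = 0; j < 3; ++j) {
      int v = F[t + j * nf];
      for (int k = 0; k < 3; ++k) {
        double x = V[v + k * nv];
        if (x < lo[k]) lo[k] = x;
        if (x > hi[k]) hi[k] = x;
      }
    }
  }

  double centroid(int t, int axis) const {
    return (V[F[t] + axis*nv] + V[F[t + nf] + axis*nv] + V[F[t + 2*nf] + axis*nv]) / 3.0;
  }

  int build(int begin, int end) {
    Node nd;
    for (int k = 0; k < 3; ++k) { nd.lo[k] = R_PosInf; nd.hi[k] = R_NegInf; }
    double tlo[3], thi[3];
    for (int i = begin; i < end; ++i) {
      tri_bounds(tri[i], tlo, thi);
      for (int k = 0; k < 3; ++k) {
        if (tlo[k] < nd.lo[k]) nd.lo[k] = tlo[k];
        if (thi[k] > nd.hi[k]) nd.hi[k] = thi[k];
      }
    }
    int me = (int) nodes.size();
    nodes.push_back(nd);
    if (end - begin <= 4) {
      nodes[me].left = nodes[me].right = -1;
      nodes[me].begin = begin; nodes[me].end = end;
      // ascending order inside the leaf keeps the lowest-index tie-break cheap
      std::sort(tri.begin() + begin, tri.begin() + end);
      return me;
    }
    int axis = 0;
    double ext = nd.hi[0] - nd.lo[0];
    for (int k = 1; k < 3; ++k)
      if (nd.hi[k] - nd.lo[k] > ext) { ext = nd.hi[k] - nd.lo[k]; axis = k; }
    int mid = (begin + end) / 2;
    std::nth_element(tri.begin() + begin, tri.begin() + mid, tri.begin() + end,
                     [&](int a, int b) { return centroid(a, axis) < centroid(b, axis); });
    int l = build(begin, mid);
    int r = build(mid, end);
    nodes[me].left = l; nodes[me].right = r;
    nodes[me].begin = nodes[me].end = -1;
    return me;
  }

  double box_dist2(int n, const double *p) const {
    double d2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      double d = 0.0;
      if (p[k] < nodes[n].lo[k]) d = nodes[n].lo[k] - p[k];
      else if (p[k] > nodes[n].hi[k]) d = p[k] - nodes[n].hi[k];
      d2 += d * d;
    }
    return d2;
  }

  void query(int n, const double *p, double &best_d2, int &best_tri,
             double *best_pt) const {
    const Node &nd = nodes[n];
    if (nd.left < 0) {
      double a[3], b[3], c[3], q[3];
      for (int i = nd.begin; i < nd.end; ++i) {
        int t = tri[i];
        for (int k = 0; k < 3; ++k) {
          a[k] = V[F[t]          + k*nv];
          b[k] = V[F[t + nf]     + k*nv];
          c[k] = V[F[t + 2*nf]   + k*nv];
        }
        closest_on_triangle(p, a, b, c, q);
        double dx = q[0]-p[0], dy = q[1]-p[1], dz = q[2]-p[2];
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 < best_d2 || (d2 == best_d2 && t < best_tri)) {
          best_d2 = d2; best_tri = t;
          best_pt[0] = q[0]; best_pt[1] = q[1]; best_pt[2] = q[2];
        }
      }
      return;
    }
    double dl = box_dist2(nd.left, p), dr = box_dist2(nd.right, p);
    int first = nd.left, second = nd.right;
    double dfirst = dl, dsecond = dr;
    if (dr < dl) { first = nd.right; second = nd.left; dfirst = dr; dsecond = dl; }
    if (dfirst <= best_d2) query(first, p, best_d2, best_tri, best_pt);
    if (dsecond <= best_d2) query(second, p, best_d2, best_tri, best_pt);
  }
};

static Tree *make_tree(NumericMatrix V, IntegerMatrix F) {
  int nv = V.nrow(), nf = F.nrow();
  if (nf < 1) stop("mesh has no faces");
  Tree *tree = new Tree();
  tree->Vstore.assign(REAL(V), REAL(V) + (size_t) nv * 3);
  tree->V = tree->Vstore.data(); tree->nv = nv;
  tree->Fstore.resize((size_t) nf * 3);
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < nf; ++i) tree->Fstore[i + (size_t) j * nf] = F(i, j) - 1;
  tree->F = tree->Fstore.data(); tree->nf = nf;
  tree->tri.resize(nf);
  for (int i = 0; i < nf; ++i) tree->tri[i] = i;
  tree->nodes.reserve(2 * nf / 4 + 8);
  tree->build(0, nf);
  return tree;
}

static List tree_query(const Tree &tree, NumericMatrix Q) {
  int nq = Q.nrow(), nf = tree.nf;
  NumericMatrix P(nq, 3);
  IntegerVector face(nq);
  NumericVector dist2(nq);
  double p[3], best_pt[3];
  for (int i = 0; i < nq; ++i) {
    p[0] = Q(i, 0); p[1] = Q(i, 1); p[2] = Q(i, 2);
    double best_d2 = R_PosInf;
    int best_tri = nf;
    tree.query(0, p, best_d2, best_tri, best_pt);
    P(i, 0) = best_pt[0]; P(i, 1) = best_pt[1]; P(i, 2) = best_pt[2];
    face[i] = best_tri + 1;
    dist2[i] = best_d2;
  }
  return List::create(_["point"] = P, _["face"] = face, _["dist2"] = dist2);
}

// [[Rcpp::export(name = ".cp_mesh_query")]]
List cp_mesh_query(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  Tree *tree = make_tree(V, F);
  List out = tree_query(*tree, Q);
  delete tree;
  return out;
}

// [[Rcpp::export(name = ".cp_build_tree")]]
SEXP cp_build_tree(NumericMatrix V, IntegerMatrix F) {
  XPtr<Tree> ptr(make_tree(V, F), true);
  return ptr;
}

// [[Rcpp::export(name = ".cp_query_tree")]]
List cp_query_tree(SEXP tree_ptr, NumericMatrix Q) {
  XPtr<Tree> ptr(tree_ptr);
  return tree_query(*ptr, Q);
}
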