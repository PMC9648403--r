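// Halfedge mesh kernel, finite-support convolution field, sizing evaluation
// and the incremental remeshing passes. Hot loops live here; the R layer
// owns I/O, fixtures and the growth driver.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
#include <unordered_map>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------- halfedge

struct HEMesh {
  // vertices
  std::vector<double> vx, vy, vz;
  std::vector<int> vhe;      // one outgoing halfedge, -1 when dead
  std::vector<char> valive;
  std::vector<int> vowner;   // owning skeleton node id (0 = unassigned)
  std::vector<char> vbound;  // vertex has reached the iso-surface and tracks it
  // halfedges (explicit twins: collapse re-splices twin pairs)
  std::vector<int> htwin, hnext, horig, hface;
  std::vector<char> halive;
  // faces
  std::vector<int> fhe;
  std::vector<char> falive;
  // free-index pools for deleted elements
  std::vector<int> vfree, hfree, ffree;
  int nV = 0, nE = 0, nF = 0;

  int n_vslots() const { return (int)vx.size(); }
  int n_hslots() const { return (int)htwin.size(); }
  int n_fslots() const { return (int)fhe.size(); }

  int new_vertex(double x, double y, double z) {
    int v;
    if (!vfree.empty()) { v = vfree.back(); vfree.pop_back();
      vx[v] = x; vy[v] = y; vz[v] = z; valive[v] = 1; vhe[v] = -1; vowner[v] = 0;
      vbound[v] = 0;
    } else {
      v = n_vslots();
      vx.push_back(x); vy.push_back(y); vz.push_back(z);
      vhe.push_back(-1); valive.push_back(1); vowner.push_back(0);
      vbound.push_back(0);
    }
    ++nV; return v;
  }
  int new_halfedge() {
    int h;
    if (!hfree.empty()) { h = hfree.back(); hfree.pop_back();
      htwin[h] = hnext[h] = horig[h] = hface[h] = -1; halive[h] = 1;
    } else {
      h = n_hslots();
      htwin.push_back(-1); hnext.push_back(-1); horig.push_back(-1);
      hface.push_back(-1); halive.push_back(1);
    }
    return h;
  }
  int new_face() {
    int f;
    if (!ffree.empty()) { f = ffree.back(); ffree.pop_back(); fhe[f] = -1; falive[f] = 1; }
    else { f = n_fslots(); fhe.push_back(-1); falive.push_back(1); }
    ++nF; return f;
  }
  void kill_vertex(int v)   { valive[v] = 0; vhe[v] = -1; vfree.push_back(v); --nV; }
  void kill_halfedge(int h) { halive[h] = 0; hfree.push_back(h); }
  void kill_face(int f)     { falive[f] = 0; ffree.push_back(f); --nF; }

  int head(int h) const { int t = htwin[h]; return t >= 0 ? horig[t] : horig[hnext[h]]; }
  bool closed_edge(int h) const { return htwin[h] >= 0; }

  double dist(int a, int b) const {
    double dx = vx[a]-vx[b], dy = vy[a]-vy[b], dz = vz[a]-vz[b];
    return std::sqrt(dx*dx + dy*dy + dz*dz);
  }
  // canonical edge handle: the smaller halfedge index of a twin pair
  int canon(int h) const { int t = htwin[h]; return (t >= 0 && t < h) ? t : h; }

  // ordered one-ring (neighbour vertices); returns false if traversal
  // hits a boundary or fails to close (non-manifold fan)
  bool one_ring(int v, std::vector<int>& out) const {
    out.clear();
    int h0 = vhe[v];
    if (h0 < 0) return false;
    int h = h0;
    int guard = n_hslots() + 1;
    do {
      if (h < 0 || !halive[h] || horig[h] != v) return false;
      int t = htwin[h];
      if (t < 0) return false;
      out.push_back(horig[t]);
      h = hnext[t];
      if (--guard == 0) return false;
    } while (h != h0);
    return true;
  }

  int valence(int v) const {
    std::vector<int> r;
    if (!one_ring(v, r)) return -1;
    return (int)r.size();
  }

  void face_verts(int f, int vv[3]) const {
    int h = fhe[f];
    vv[0] = horig[h]; vv[1] = horig[hnext[h]]; vv[2] = horig[hnext[hnext[h]]];
  }
  void face_normal(int f, double n[3]) const {
    int vv[3]; face_verts(f, vv);
    double ax = vx[vv[1]]-vx[vv[0]], ay = vy[vv[1]]-vy[vv[0]], az = vz[vv[1]]-vz[vv[0]];
    double bx = vx[vv[2]]-vx[vv[0]], by = vy[vv[2]]-vy[vv[0]], bz = vz[vv[2]]-vz[vv[0]];
    n[0] = ay*bz - az*by; n[1] = az*bx - ax*bz; n[2] = ax*by - ay*bx;
  }
};

static HEMesh* get_mesh(SEXP xp) {
  Rcpp::XPtr<HEMesh> p(xp);
  return p.get();
}

static void check_edge_handle(const HEMesh* m, int h) {
  if (h < 0 || h >= m->n_hslots() || !m->halive[h])
    stop("stale or invalid edge handle");
}
static void check_vertex_handle(const HEMesh* m, int v) {
  if (v < 0 || v >= m->n_vslots() || !m->valive[v])
    stop("stale or invalid vertex handle");
}

// [[Rcpp::export]]
SEXP he_build(NumericMatrix V, IntegerMatrix F, bool allow_boundary = false) {
  if (V.ncol() != 3) stop("V must be n x 3");
  if (F.ncol() != 3) stop("F must be m x 3 (triangles)");
  HEMesh* m = new HEMesh();
  int nv = V.nrow(), nf = F.nrow();
  for (int i = 0; i < nv; ++i) m->new_vertex(V(i,0), V(i,1), V(i,2));
  // directed edge -> halfedge
  std::unordered_map<long long, int> dir;
  dir.reserve(nf * 3 * 2);
  auto key = [nv](int a, int b) { return (long long)a * (long long)(nv + 1) + b; };
  for (int f = 0; f < nf; ++f) {
    int fid = m->new_face();
    int hh[3];
    int vv[3] = { F(f,0) - 1, F(f,1) - 1, F(f,2) - 1 };
    for (int k = 0; k < 3; ++k) {
      if (vv[k] < 0 || vv[k] >= nv) { delete m; stop("face references unknown vertex"); }
      if (vv[k] == vv[(k+1)%3]) { delete m; stop("degenerate face (repeated vertex)"); }
    }
    for (int k = 0; k < 3; ++k) {
      int a = vv[k], b = vv[(k+1)%3];
      if (dir.count(key(a,b))) { delete m; stop("non-manifold or inconsistently oriented faces (duplicate directed edge)"); }
      int h = m->new_halfedge();
      dir[key(a,b)] = h;
      m->horig[h] = a; m->hface[h] = fid;
      m->vhe[a] = h;
      hh[k] = h;
      auto it = dir.find(key(b,a));
      if (it != dir.end()) { m->htwin[h] = it->second; m->htwin[it->second] = h; }
    }
    m->hnext[hh[0]] = hh[1]; m->hnext[hh[1]] = hh[2]; m->hnext[hh[2]] = hh[0];
    m->fhe[fid] = hh[0];
  }
  int boundary = 0;
  for (int h = 0; h < m->n_hslots(); ++h)
    if (m->halive[h] && m->htwin[h] < 0) ++boundary;
  if (boundary > 0 && !allow_boundary) {
    delete m;
    stop("mesh has %d boundary halfedges; a closed surface is required", boundary);
  }
  // edge count: twin pairs count once, boundary halfedges once
  int ne = 0;
  for (int h = 0; h < m->n_hslots(); ++h)
    if (m->halive[h] && (m->htwin[h] < 0 || m->htwin[h] > h)) ++ne;
  m->nE = ne;
  return Rcpp::XPtr<HEMesh>(m, true);
}

// [[Rcpp::export]]
SEXP he_clone(SEXP xp) {
  HEMesh* m = get_mesh(xp);
  HEMesh* c = new HEMesh(*m);
  return Rcpp::XPtr<HEMesh>(c, true);
}

// [[Rcpp::export]]
IntegerVector he_counts(SEXP xp) {
  HEMesh* m = get_mesh(xp);
  return IntegerVector::create(_["V"] = m->nV, _["E"] = m->nE, _["F"] = m->nF);
}

// [[Rcpp::export]]
IntegerVector he_live_vertices(SEXP xp) {
  HEMesh* m = get_mesh(xp);
  std::vector<int> out;
  for (int v = 0; v < m->n_vslots(); ++v) if (m->valive[v]) out.push_back(v + 1);
  return wrap(out);
}

// [[Rcpp::export]]
NumericMatrix he_positions(SEXP xp, IntegerVector vids) {
  HEMesh* m = get_mesh(xp);
  NumericMatrix out(vids.size(), 3);
  for (int i = 0; i < vids.size(); ++i) {
    int v = vids[i] - 1;
    check_vertex_handle(m, v);
    out(i,0) = m->vx[v]; out(i,1) = m->vy[v]; out(i,2) = m->vz[v];
  }
  return out;
}

// [[Rcpp::export]]
void he_set_positions(SEXP xp, IntegerVector vids, NumericMatrix P) {
  HEMesh* m = get_mesh(xp);
  if (P.nrow() != vids.size() || P.ncol() != 3) stop("P must be length(vids) x 3");
  for (int i = 0; i < vids.size(); ++i) {
    int v = vids[i] - 1;
    check_vertex_handle(m, v);
    m->vx[v] = P(i,0); m->vy[v] = P(i,1); m->vz[v] = P(i,2);
  }
}

// [[Rcpp::export]]
IntegerVector he_owners(SEXP xp, IntegerVector vids) {
  HEMesh* m = get_mesh(xp);
  IntegerVector out(vids.size());
  for (int i = 0; i < vids.size(); ++i) {
    int v = vids[i] - 1;
    check_vertex_handle(m, v);
    out[i] = m->vowner[v];
  }
  return out;
}

// [[Rcpp::export]]
void he_set_owners(SEXP xp, IntegerVector vids, IntegerVector owners) {
  HEMesh* m = get_mesh(xp);
  if (owners.size() != vids.size()) stop("length mismatch");
  for (int i = 0; i < vids.size(); ++i) {
    int v = vids[i] - 1;
    check_vertex_handle(m, v);
    m->vowner[v] = owners[i];
  }
}

// compact live elements; returns V (k x 3), F (m x 3, 1-based into V),
// vmap (original 1-based vertex handles per compact row)
// [[Rcpp::export]]
List he_compact(SEXP xp) {
  HEMesh* m = get_mesh(xp);
  std::vector<int> vmap(m->n_vslots(), -1), vids;
  for (int v = 0; v < m->n_vslots(); ++v)
    if (m->valive[v]) { vmap[v] = (int)vids.size(); vids.push_back(v); }
  NumericMatrix V((int)vids.size(), 3);
  for (size_t i = 0; i < vids.size(); ++i) {
    V(i,0) = m->vx[vids[i]]; V(i,1) = m->vy[vids[i]]; V(i,2) = m->vz[vids[i]];
  }
  std::vector<int> faces;
  for (int f = 0; f < m->n_fslots(); ++f) {
    if (!m->falive[f]) continue;
    int vv[3]; m->face_verts(f, vv);
    for (int k = 0; k < 3; ++k) faces.push_back(vmap[vv[k]] + 1);
  }
  IntegerMatrix F((int)faces.size() / 3, 3);
  for (int i = 0; i < F.nrow(); ++i)
    for (int k = 0; k < 3; ++k) F(i,k) = faces[3*i + k];
  IntegerVector vm((int)vids.size());
  for (size_t i = 0; i < vids.size(); ++i) vm[i] = vids[i] + 1;
  return List::create(_["V"] = V, _["F"] = F, _["vmap"] = vm);
}

// canonical edge handles with endpoints and lengths
// [[Rcpp::export]]
List he_edges(SEXP xp) {
  HEMesh* m = get_mesh(xp);
  std::vector<int> hs, va, vb;
  std::vector<double> len;
  for (int h = 0; h < m->n_hslots(); ++h) {
    if (!m->halive[h]) continue;
    if (m->htwin[h] >= 0 && m->htwin[h] < h) continue;
    int a = m->horig[h], b = m->head(h);
    hs.push_back(h + 1); va.push_back(a + 1); vb.push_back(b + 1);
    len.push_back(m->dist(a, b));
  }
  return List::create(_["edge"] = wrap(hs), _["v0"] = wrap(va),
                      _["v1"] = wrap(vb), _["length"] = wrap(len));
}

// [[Rcpp::export]]
int he_edge_between(SEXP xp, int v0, int v1) {
  HEMesh* m = get_mesh(xp);
  check_vertex_handle(m, v0 - 1);
  check_vertex_handle(m, v1 - 1);
  int a = v0 - 1, b = v1 - 1;
  int h0 = m->vhe[a], h = h0;
  int guard = m->n_hslots() + 1;
  if (h0 < 0) return -1;
  do {
    if (m->head(h) == b) return m->canon(h) + 1;
    int t = m->htwin[h];
    if (t < 0) return -1;
    h = m->hnext[t];
  } while (h != h0 && --guard > 0);
  return -1;
}

// [[Rcpp::export]]
IntegerVector he_edge_verts(SEXP xp, int edge) {
  HEMesh* m = get_mesh(xp);
  int h = edge - 1;
  check_edge_handle(m, h);
  return IntegerVector::create(m->horig[h] + 1, m->head(h) + 1);
}

// [[Rcpp::export]]
IntegerVector he_one_ring(SEXP xp, int v) {
  HEMesh* m = get_mesh(xp);
  check_vertex_handle(m, v - 1);
  std::vector<int> r;
  if (!m->one_ring(v - 1, r))
    stop("one-ring traversal failed (boundary or non-manifold vertex)");
  IntegerVector out((int)r.size());
  for (size_t i = 0; i < r.size(); ++i) out[i] = r[i] + 1;
  return out;
}

// --------------------------------------------------------- local operators

static void set_owner_from_nearer(HEMesh* m, int vnew, int a, int b,
                                  double px, double py, double pz) {
  double da = (m->vx[a]-px)*(m->vx[a]-px) + (m->vy[a]-py)*(m->vy[a]-py) + (m->vz[a]-pz)*(m->vz[a]-pz);
  double db = (m->vx[b]-px)*(m->vx[b]-px) + (m->vy[b]-py)*(m->vy[b]-py) + (m->vz[b]-pz)*(m->vz[b]-pz);
  int oa = m->vowner[a], ob = m->vowner[b];
  if (da < db) m->vowner[vnew] = oa;
  else if (db < da) m->vowner[vnew] = ob;
  else m->vowner[vnew] = (oa != 0 && (ob == 0 || oa <= ob)) ? oa : ob;
}

// split edge at position (default midpoint); returns new vertex handle (1-based)
// [[Rcpp::export]]
int he_split_edge(SEXP xp, int edge, Nullable<NumericVector> position = R_NilValue) {
  HEMesh* m = get_mesh(xp);
  int h = edge - 1;
  check_edge_handle(m, h);
  if (!m->closed_edge(h)) stop("cannot split a boundary edge");
  int t = m->htwin[h];
  int a = m->horig[h], b = m->horig[t];
  double px, py, pz;
  if (position.isNotNull()) {
    NumericVector p(position);
    if (p.size() != 3) stop("position must be length 3");
    px = p[0]; py = p[1]; pz = p[2];
  } else {
    px = 0.5*(m->vx[a] + m->vx[b]); py = 0.5*(m->vy[a] + m->vy[b]); pz = 0.5*(m->vz[a] + m->vz[b]);
  }
  int f0 = m->hface[h], f1 = m->hface[t];
  int hbc = m->hnext[h],  hca = m->hnext[hbc];
  int had = m->hnext[t],  hdb = m->hnext[had];
  int c = m->horig[hca], d = m->horig[hdb];

  int mv = m->new_vertex(px, py, pz);
  set_owner_from_nearer(m, mv, a, b, px, py, pz);
  m->vbound[mv] = m->vbound[a] && m->vbound[b];

  // new halfedge pairs: (m->b, b->m), (m->c, c->m), (m->d, d->m)
  int h1 = m->new_halfedge(), t1 = m->new_halfedge();
  int h2 = m->new_halfedge(), t2 = m->new_halfedge();
  int h3 = m->new_halfedge(), t3 = m->new_halfedge();
  m->htwin[h1] = t1; m->htwin[t1] = h1;
  m->htwin[h2] = t2; m->htwin[t2] = h2;
  m->htwin[h3] = t3; m->htwin[t3] = h3;
  m->horig[h1] = mv; m->horig[t1] = b;
  m->horig[h2] = mv; m->horig[t2] = c;
  m->horig[h3] = mv; m->horig[t3] = d;

  int f2 = m->new_face(), f3 = m->new_face();

  // h: a->m stays in f0 (a, m, c): h -> h2(m->c) -> hca(c->a)
  m->hnext[h] = h2;  m->hnext[h2] = hca; m->hnext[hca] = h;
  m->hface[h] = f0;  m->hface[h2] = f0;  m->hface[hca] = f0; m->fhe[f0] = h;
  // f2 (m, b, c): h1(m->b) -> hbc(b->c) -> t2(c->m)
  m->hnext[h1] = hbc; m->hnext[hbc] = t2; m->hnext[t2] = h1;
  m->hface[h1] = f2;  m->hface[hbc] = f2; m->hface[t2] = f2; m->fhe[f2] = h1;
  // t: m->a stays in f1 (m, a, d): t -> had(a->d) -> t3(d->m)
  m->horig[t] = mv;
  m->hnext[t] = had; m->hnext[had] = t3; m->hnext[t3] = t;
  m->hface[t] = f1;  m->hface[had] = f1; m->hface[t3] = f1; m->fhe[f1] = t;
  // f3 (b, m, d): t1(b->m) -> h3(m->d) -> hdb(d->b)
  m->hnext[t1] = h3; m->hnext[h3] = hdb; m->hnext[hdb] = t1;
  m->hface[t1] = f3; m->hface[h3] = f3;  m->hface[hdb] = f3; m->fhe[f3] = t1;

  m->vhe[mv] = h1;
  m->vhe[a] = h; m->vhe[b] = t1; m->vhe[c] = hca; m->vhe[d] = hdb;
  m->nE += 3;
  return mv + 1;
}

// collapse legality: link condition + tetrahedron/fold guard + normal flip
static bool collapse_ok(HEMesh* m, int h, double* mid, bool skip_normal_test = false) {
  int t = m->htwin[h];
  if (t < 0) return false;
  int a = m->horig[h], b = m->horig[t];
  int c = m->horig[m->hnext[m->hnext[h]]];
  int d = m->horig[m->hnext[m->hnext[t]]];
  if (m->nV <= 4) return false;
  std::vector<int> ra, rb;
  if (!m->one_ring(a, ra) || !m->one_ring(b, rb)) return false;
  // common neighbours must be exactly {c, d}
  int common = 0;
  for (int u : ra) {
    for (int v : rb) {
      if (u == v) {
        if (u != c && u != d) return false;
        ++common;
      }
    }
  }
  if (common != 2) return false;
  // fold guard: if edge (c, d) exists and its two faces are exactly the
  // endpoint-capped triangles {a,c,d} / {b,c,d}, collapsing folds the mesh
  bool cd = false;
  {
    std::vector<int> rc;
    if (!m->one_ring(c, rc)) return false;
    for (int u : rc) if (u == d) { cd = true; break; }
  }
  if (cd) {
    // locate edge cd and inspect its opposite vertices
    int h0 = m->vhe[c], hh = h0;
    int guard = m->n_hslots() + 1;
    do {
      if (m->head(hh) == d) {
        int o1 = m->horig[m->hnext[m->hnext[hh]]];
        int o2 = m->horig[m->hnext[m->hnext[m->htwin[hh]]]];
        if ((o1 == a && o2 == b) || (o1 == b && o2 == a)) return false;
        break;
      }
      hh = m->hnext[m->htwin[hh]];
    } while (hh != h0 && --guard > 0);
  }
  // normal-flip test on surviving faces incident to a or b
  mid[0] = 0.5*(m->vx[a] + m->vx[b]);
  mid[1] = 0.5*(m->vy[a] + m->vy[b]);
  mid[2] = 0.5*(m->vz[a] + m->vz[b]);
  int f0 = m->hface[h], f1 = m->hface[t];
  for (int end = 0; end < 2; ++end) {
    int v = end == 0 ? a : b;
    int h0 = m->vhe[v], hh = h0;
    int guard = m->n_hslots() + 1;
    do {
      int f = m->hface[hh];
      if (f != f0 && f != f1) {
        int vv[3]; m->face_verts(f, vv);
        double ox[3], oy[3], oz[3];
        for (int k = 0; k < 3; ++k) { ox[k] = m->vx[vv[k]]; oy[k] = m->vy[vv[k]]; oz[k] = m->vz[vv[k]]; }
        double n_old[3];
        m->face_normal(f, n_old);
        double nx[3], ny[3], nz[3];
        for (int k = 0; k < 3; ++k) {
          if (vv[k] == a || vv[k] == b) { nx[k] = mid[0]; ny[k] = mid[1]; nz[k] = mid[2]; }
          else { nx[k] = ox[k]; ny[k] = oy[k]; nz[k] = oz[k]; }
        }
        double ux = nx[1]-nx[0], uy = ny[1]-ny[0], uz = nz[1]-nz[0];
        double wx = nx[2]-nx[0], wy = ny[2]-ny[0], wz = nz[2]-nz[0];
        double n_new[3] = { uy*wz - uz*wy, uz*wx - ux*wz, ux*wy - uy*wx };
        double dot = n_old[0]*n_new[0] + n_old[1]*n_new[1] + n_old[2]*n_new[2];
        double nn = n_new[0]*n_new[0] + n_new[1]*n_new[1] + n_new[2]*n_new[2];
        if (!skip_normal_test && (dot < 0 || nn == 0)) return false;
      }
      hh = m->hnext[m->htwin[hh]];
    } while (hh != h0 && --guard > 0);
  }
  return true;
}

// [[Rcpp::export]]
bool he_collapse_ok(SEXP xp, int edge) {
  HEMesh* m = get_mesh(xp);
  int h = edge - 1;
  check_edge_handle(m, h);
  double mid[3];
  return collapse_ok(m, h, mid);
}

// collapse edge to its midpoint; returns surviving vertex handle or -1
// [[Rcpp::export]]
int he_collapse_edge(SEXP xp, int edge, bool skip_normal_test = false) {
  HEMesh* m = get_mesh(xp);
  int h = edge - 1;
  check_edge_handle(m, h);
  double mid[3];
  if (!collapse_ok(m, h, mid, skip_normal_test)) return -1;
  int t = m->htwin[h];
  int a = m->horig[h], b = m->horig[t];
  int f0 = m->hface[h], f1 = m->hface[t];
  int hbc = m->hnext[h],  hca = m->hnext[hbc];
  int had = m->hnext[t],  hdb = m->hnext[had];
  int c = m->horig[hca], d = m->horig[hdb];
  int t_bc = m->htwin[hbc], t_ca = m->htwin[hca];
  int t_ad = m->htwin[had], t_db = m->htwin[hdb];

  // owner of the surviving vertex: both endpoints are equidistant from the
  // midpoint, so the tie-break keeps the lower owning node id
  int oa = m->vowner[a], ob = m->vowner[b];
  int owner = (oa != 0 && (ob == 0 || oa <= ob)) ? oa : ob;
  char bound = m->vbound[a] && m->vbound[b];

  // re-origin all halfedges leaving b to a
  {
    int h0 = m->vhe[b], hh = h0;
    int guard = m->n_hslots() + 1;
    do {
      m->horig[hh] = a;
      hh = m->hnext[m->htwin[hh]];
    } while (hh != h0 && --guard > 0);
  }
  // splice twins across the two dying faces (edges merge pairwise)
  m->htwin[t_bc] = t_ca; m->htwin[t_ca] = t_bc;
  m->htwin[t_ad] = t_db; m->htwin[t_db] = t_ad;

  m->vx[a] = mid[0]; m->vy[a] = mid[1]; m->vz[a] = mid[2];
  m->vowner[a] = owner;
  m->vbound[a] = bound;
  m->vhe[a] = t_ca; // a -> c
  m->vhe[c] = t_bc; // c -> a (was c -> b)
  m->vhe[d] = t_ad; // d -> a

  m->kill_halfedge(h); m->kill_halfedge(t);
  m->kill_halfedge(hbc); m->kill_halfedge(hca);
  m->kill_halfedge(had); m->kill_halfedge(hdb);
  m->kill_face(f0); m->kill_face(f1);
  m->kill_vertex(b);
  m->nE -= 3;
  return a + 1;
}

// [[Rcpp::export]]
bool he_flip_edge(SEXP xp, int edge) {
  HEMesh* m = get_mesh(xp);
  int h = edge - 1;
  check_edge_handle(m, h);
  if (!m->closed_edge(h)) stop("cannot flip a boundary edge");
  int t = m->htwin[h];
  int a = m->horig[h], b = m->horig[t];
  int f0 = m->hface[h], f1 = m->hface[t];
  int hbc = m->hnext[h],  hca = m->hnext[hbc];
  int had = m->hnext[t],  hdb = m->hnext[had];
  int c = m->horig[hca], d = m->horig[hdb];
  // legality: would the flip duplicate an existing edge c-d?
  {
    std::vector<int> rc;
    if (!m->one_ring(c, rc)) return false;
    for (int u : rc) if (u == d) return false;
  }
  // rewire: new edge c->d / d->c; faces (a, d, c) and (b, c, d)
  m->horig[h] = d; m->horig[t] = c; // h: d->c, t: c->d
  m->hnext[had] = h;  m->hnext[h] = hca;  m->hnext[hca] = had;
  m->hface[had] = f0; m->hface[h] = f0;   m->hface[hca] = f0; m->fhe[f0] = had;
  m->hnext[hbc] = t;  m->hnext[t] = hdb;  m->hnext[hdb] = hbc;
  m->hface[hbc] = f1; m->hface[t] = f1;   m->hface[hdb] = f1; m->fhe[f1] = hbc;
  m->vhe[a] = had; m->vhe[b] = hbc; m->vhe[c] = t; m->vhe[d] = h;
  return true;
}

// ------------------------------------------------------------- audits

// [[Rcpp::export]]
bool he_is_watertight(SEXP xp) {
  HEMesh* m = get_mesh(xp);
  for (int h = 0; h < m->n_hslots(); ++h) {
    if (!m->halive[h]) continue;
    int t = m->htwin[h];
    if (t < 0 || !m->halive[t] || m->htwin[t] != h) return false;
  }
  return true;
}

// [[Rcpp::export]]
bool he_is_manifold(SEXP xp) {
  HEMesh* m = get_mesh(xp);
  if (!he_is_watertight(xp)) return false; // an edge without 2 faces fails
  // every vertex fan must be a single cycle covering all its halfedges
  std::vector<int> deg(m->n_vslots(), 0);
  for (int h = 0; h < m->n_hslots(); ++h)
    if (m->halive[h]) ++deg[m->horig[h]];
  std::vector<int> ring;
  for (int v = 0; v < m->n_vslots(); ++v) {
    if (!m->valive[v]) continue;
    if (!m->one_ring(v, ring)) return false;
    if ((int)ring.size() != deg[v]) return false;
  }
  return true;
}

// structural audit: orientation coherence, 3-cycles, Euler characteristic
// [[Rcpp::export]]
List he_audit(SEXP xp) {
  HEMesh* m = get_mesh(xp);
  bool ok = true;
  std::string msg = "";
  for (int h = 0; h < m->n_hslots() && ok; ++h) {
    if (!m->halive[h]) continue;
    int t = m->htwin[h];
    if (t < 0 || !m->halive[t] || m->htwin[t] != h) { ok = false; msg = "twin involution broken"; break; }
    if (m->horig[t] != m->horig[m->hnext[h]]) { ok = false; msg = "orientation incoherent"; break; }
    if (m->hnext[m->hnext[m->hnext[h]]] != h) { ok = false; msg = "face cycle not a triangle"; break; }
    if (m->hface[m->hnext[h]] != m->hface[h]) { ok = false; msg = "face pointer mismatch"; break; }
    if (!m->valive[m->horig[h]]) { ok = false; msg = "halfedge from dead vertex"; break; }
  }
  if (ok) {
    for (int f = 0; f < m->n_fslots(); ++f) {
      if (!m->falive[f]) continue;
      if (m->fhe[f] < 0 || !m->halive[m->fhe[f]] || m->hface[m->fhe[f]] != f) {
        ok = false; msg = "face anchor broken"; break;
      }
      int vv[3]; m->face_verts(f, vv);
      if (vv[0] == vv[1] || vv[1] == vv[2] || vv[0] == vv[2]) {
        ok = false; msg = "degenerate face"; break;
      }
    }
  }
  bool manifold = ok && he_is_manifold(xp);
  int euler = m->nV - m->nE + m->nF;
  return List::create(
    _["structure_ok"] = ok, _["message"] = msg,
    _["manifold"] = manifold, _["watertight"] = ok && he_is_watertight(xp),
    _["euler"] = euler);
}

// [[Rcpp::export]]
IntegerVector he_valences(SEXP xp, IntegerVector vids) {
  HEMesh* m = get_mesh(xp);
  IntegerVector out(vids.size());
  for (int i = 0; i < vids.size(); ++i) {
    int v = vids[i] - 1;
    check_vertex_handle(m, v);
    out[i] = m->valence(v);
  }
  return out;
}

// [[Rcpp::export]]
double he_min_triangle_angle(SEXP xp) {
  HEMesh* m = get_mesh(xp);
  double best = M_PI;
  for (int f = 0; f < m->n_fslots(); ++f) {
    if (!m->falive[f]) continue;
    int vv[3]; m->face_verts(f, vv);
    double px[3] = { m->vx[vv[0]], m->vx[vv[1]], m->vx[vv[2]] };
    double py[3] = { m->vy[vv[0]], m->vy[vv[1]], m->vy[vv[2]] };
    double pz[3] = { m->vz[vv[0]], m->vz[vv[1]], m->vz[vv[2]] };
    for (int k = 0; k < 3; ++k) {
      int i = k, j = (k+1)%3, l = (k+2)%3;
      double ux = px[j]-px[i], uy = py[j]-py[i], uz = pz[j]-pz[i];
      double wx = px[l]-px[i], wy = py[l]-py[i], wz = pz[l]-pz[i];
      double nu = std::sqrt(ux*ux+uy*uy+uz*uz), nw = std::sqrt(wx*wx+wy*wy+wz*wz);
      if (nu == 0 || nw == 0) return 0.0;
      double cosang = (ux*wx+uy*wy+uz*wz) / (nu*nw);
      cosang = std::max(-1.0, std::min(1.0, cosang));
      double ang = std::acos(cosang);
      if (ang < best) best = ang;
    }
  }
  return best * 180.0 / M_PI;
}

// shortest incident edge length per vertex
// [[Rcpp::export]]
NumericVector he_min_incident_edge(SEXP xp, IntegerVector vids) {
  HEMesh* m = get_mesh(xp);
  NumericVector out(vids.size());
  std::vector<int> ring;
  for (int i = 0; i < vids.size(); ++i) {
    int v = vids[i] - 1;
    check_vertex_handle(m, v);
    if (!m->one_ring(v, ring)) stop("one-ring traversal failed");
    double best = std::numeric_limits<double>::infinity();
    for (int u : ring) best = std::min(best, m->dist(v, u));
    out[i] = best;
  }
  return out;
}

// ------------------------------------------------------- convolution field

struct Sources {
  int n = 0;
  std::vector<double> ax, ay, az, bx, by, bz, d, R, lam, len, ux, uy, uz;
  double maxR = 0, mind = 0;
  // culling grid: cell -> source indices; cell size = max R_i
  double cell = 1.0;
  std::unordered_map<long long, std::vector<int> > grid;

  static long long key(int i, int j, int k) {
    return ((long long)(i + 1048576) << 42) ^ ((long long)(j + 1048576) << 21) ^ (long long)(k + 1048576);
  }
  void build(const NumericMatrix& S) {
    n = S.nrow();
    if (n > 0 && S.ncol() < 9) stop("sources must have 9 columns: ax ay az bx by bz d R lambda");
    ax.resize(n); ay.resize(n); az.resize(n); bx.resize(n); by.resize(n); bz.resize(n);
    d.resize(n); R.resize(n); lam.resize(n); len.resize(n); ux.resize(n); uy.resize(n); uz.resize(n);
    maxR = 0; mind = std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; ++i) {
      ax[i]=S(i,0); ay[i]=S(i,1); az[i]=S(i,2); bx[i]=S(i,3); by[i]=S(i,4); bz[i]=S(i,5);
      d[i]=S(i,6); R[i]=S(i,7); lam[i]=S(i,8);
      if (d[i] <= 0 || R[i] <= d[i]) stop("source %d: need 0 < d < R", i + 1);
      double dx=bx[i]-ax[i], dy=by[i]-ay[i], dz=bz[i]-az[i];
      len[i] = std::sqrt(dx*dx+dy*dy+dz*dz);
      if (len[i] > 0) { ux[i]=dx/len[i]; uy[i]=dy/len[i]; uz[i]=dz/len[i]; }
      else { ux[i]=uy[i]=uz[i]=0; }
      maxR = std::max(maxR, R[i]);
      mind = std::min(mind, d[i]);
    }
    if (n == 0) { mind = 1.0; maxR = 1.0; }
    cell = maxR > 0 ? maxR : 1.0;
    grid.clear();
    for (int i = 0; i < n; ++i) {
      double lox = std::min(ax[i],bx[i]) - R[i], hix = std::max(ax[i],bx[i]) + R[i];
      double loy = std::min(ay[i],by[i]) - R[i], hiy = std::max(ay[i],by[i]) + R[i];
      double loz = std::min(az[i],bz[i]) - R[i], hiz = std::max(az[i],bz[i]) + R[i];
      int i0 = (int)std::floor(lox/cell), i1 = (int)std::floor(hix/cell);
      int j0 = (int)std::floor(loy/cell), j1 = (int)std::floor(hiy/cell);
      int k0 = (int)std::floor(loz/cell), k1 = (int)std::floor(hiz/cell);
      for (int ii = i0; ii <= i1; ++ii)
        for (int jj = j0; jj <= j1; ++jj)
          for (int kk = k0; kk <= k1; ++kk)
            grid[key(ii,jj,kk)].push_back(i);
    }
  }
  const std::vector<int>* candidates(double x, double y, double z) const {
    auto it = grid.find(key((int)std::floor(x/cell), (int)std::floor(y/cell), (int)std::floor(z/cell)));
    return it == grid.end() ? nullptr : &it->second;
  }
  // squared distance from point to segment i
  double dist2(int i, double x, double y, double z) const {
    double px = x-ax[i], py = y-ay[i], pz = z-az[i];
    double t = 0;
    if (len[i] > 0) {
      t = (px*ux[i] + py*uy[i] + pz*uz[i]);
      t = std::max(0.0, std::min(len[i], t));
    }
    double cx = px - t*ux[i], cy = py - t*uy[i], cz = pz - t*uz[i];
    return cx*cx + cy*cy + cz*cz;
  }
};

// 16-point Gauss-Legendre nodes/weights on [-1, 1], computed once by Newton
// iteration on the Legendre polynomial
static const int GLN = 16;
static double gl_x[GLN], gl_w[GLN];
static bool gl_ready = false;
static void gl_init() {
  if (gl_ready) return;
  int n = GLN;
  for (int i = 0; i < (n + 1) / 2; ++i) {
    double x = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double pp = 0;
    for (int it = 0; it < 100; ++it) {
      double p0 = 1.0, p1 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p2 = p1; p1 = p0;
        p0 = ((2.0*j + 1.0) * x * p1 - j * p2) / (j + 1.0);
      }
      pp = n * (x * p0 - p1) / (x*x - 1.0);
      double dx = p0 / pp;
      x -= dx;
      if (std::fabs(dx) < 1e-15) break;
    }
    gl_x[i] = -x; gl_x[n-1-i] = x;
    gl_w[i] = 2.0 / ((1.0 - x*x) * pp * pp);
    gl_w[n-1-i] = gl_w[i];
  }
  gl_ready = true;
}

static inline double quartic(double r2, double R2) {
  if (r2 >= R2) return 0.0;
  double q = 1.0 - r2 / R2;
  return q * q;
}

// potential of one segment source at a point (Gauss-Legendre along the
// segment, pieces no longer than R so the narrow support is resolved)
static double seg_potential(const Sources& s, int i, double x, double y, double z) {
  double R2 = s.R[i] * s.R[i];
  if (s.dist2(i, x, y, z) >= R2) return 0.0;
  gl_init();
  double L = s.len[i];
  if (L == 0) return 0.0;
  int pieces = (int)std::ceil(L / s.R[i]);
  if (pieces < 1) pieces = 1;
  double acc = 0.0, plen = L / pieces;
  for (int p = 0; p < pieces; ++p) {
    double t0 = p * plen, half = 0.5 * plen, mid = t0 + half;
    double sub = 0.0;
    for (int k = 0; k < GLN; ++k) {
      double t = mid + half * gl_x[k];
      double qx = s.ax[i] + t * s.ux[i] - x;
      double qy = s.ay[i] + t * s.uy[i] - y;
      double qz = s.az[i] + t * s.uz[i] - z;
      sub += gl_w[k] * quartic(qx*qx + qy*qy + qz*qz, R2);
    }
    acc += sub * half;
  }
  return s.lam[i] * acc;
}

static double field_at(const Sources& s, double x, double y, double z, bool brute) {
  double acc = 0.0;
  if (brute || s.n == 0) {
    for (int i = 0; i < s.n; ++i) acc += seg_potential(s, i, x, y, z);
    return acc;
  }
  const std::vector<int>* cand = s.candidates(x, y, z);
  if (!cand) return 0.0;
  for (int i : *cand) acc += seg_potential(s, i, x, y, z);
  return acc;
}

static void grad_at(const Sources& s, double x, double y, double z, double h,
                    double g[3], bool brute) {
  g[0] = (field_at(s, x + h, y, z, brute) - field_at(s, x - h, y, z, brute)) / (2*h);
  g[1] = (field_at(s, x, y + h, z, brute) - field_at(s, x, y - h, z, brute)) / (2*h);
  g[2] = (field_at(s, x, y, z + h, brute) - field_at(s, x, y, z - h, brute)) / (2*h);
}

// [[Rcpp::export]]
NumericVector fld_value(NumericMatrix P, NumericMatrix S, bool brute = false) {
  Sources s; s.build(S);
  NumericVector out(P.nrow());
  for (int i = 0; i < P.nrow(); ++i)
    out[i] = field_at(s, P(i,0), P(i,1), P(i,2), brute);
  return out;
}

// [[Rcpp::export]]
NumericMatrix fld_gradient(NumericMatrix P, NumericMatrix S,
                           double h = -1.0, bool brute = false) {
  Sources s; s.build(S);
  if (h <= 0) h = 1e-4 * s.mind;
  NumericMatrix out(P.nrow(), 3);
  double g[3];
  for (int i = 0; i < P.nrow(); ++i) {
    // outside every support capsule the gradient is identically zero
    bool inside = false;
    if (brute) {
      for (int k = 0; k < s.n && !inside; ++k)
        inside = s.dist2(k, P(i,0), P(i,1), P(i,2)) < s.R[k]*s.R[k];
    } else {
      const std::vector<int>* cand = s.candidates(P(i,0), P(i,1), P(i,2));
      if (cand)
        for (int k : *cand) {
          if (s.dist2(k, P(i,0), P(i,1), P(i,2)) < s.R[k]*s.R[k]) { inside = true; break; }
        }
    }
    if (!inside) { out(i,0) = out(i,1) = out(i,2) = 0; continue; }
    grad_at(s, P(i,0), P(i,1), P(i,2), h, g, brute);
    out(i,0) = g[0]; out(i,1) = g[1]; out(i,2) = g[2];
  }
  return out;
}

// safeguarded descent onto the iso-surface F = T: step in the direction
// that reduces |F - T|, halving the step whenever F - T changes sign or
// the trial fails to improve
static bool project_one(const Sources& s, double T, double tol, int maxit,
                        double lstep, double h, double p[3], int* iters) {
  double F = field_at(s, p[0], p[1], p[2], false);
  double err = std::fabs(F - T);
  *iters = 0;
  if (err <= tol) return true;
  double step = lstep;
  double g[3];
  for (int it = 0; it < maxit; ++it) {
    *iters = it + 1;
    grad_at(s, p[0], p[1], p[2], h, g, false);
    double ng = std::sqrt(g[0]*g[0] + g[1]*g[1] + g[2]*g[2]);
    if (ng < 1e-300) return false; // zero gradient: cannot make progress
    double sgn = (F > T) ? 1.0 : -1.0;
    // move against the printed Eq-7 sign so that |F - T| decreases
    double dx = -sgn * step * g[0] / ng;
    double dy = -sgn * step * g[1] / ng;
    double dz = -sgn * step * g[2] / ng;
    double q[3] = { p[0] + dx, p[1] + dy, p[2] + dz };
    double Fq = field_at(s, q[0], q[1], q[2], false);
    double errq = std::fabs(Fq - T);
    if ((Fq - T) * (F - T) < 0) step *= 0.5; // bisection safeguard
    if (errq < err) {
      p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
      F = Fq; err = errq;
      if (err <= tol) return true;
    } else {
      step *= 0.5;
      if (step < 1e-12 * lstep) return false;
    }
  }
  return err <= tol;
}

// [[Rcpp::export]]
List fld_project(NumericMatrix P, NumericMatrix S, NumericVector lstep,
                 double T = 1.0, double tol = 1e-4, int maxit = 30,
                 double h = -1.0) {
  Sources s; s.build(S);
  if (h <= 0) h = 1e-4 * s.mind;
  if (lstep.size() != P.nrow()) stop("lstep must have one entry per point");
  NumericMatrix out(P.nrow(), 3);
  LogicalVector conv(P.nrow());
  IntegerVector iters(P.nrow());
  for (int i = 0; i < P.nrow(); ++i) {
    double p[3] = { P(i,0), P(i,1), P(i,2) };
    int it = 0;
    conv[i] = project_one(s, T, tol, maxit, lstep[i], h, p, &it);
    out(i,0) = p[0]; out(i,1) = p[1]; out(i,2) = p[2];
    iters[i] = it;
  }
  return List::create(_["position"] = out, _["converged"] = conv, _["iterations"] = iters);
}

// ------------------------------------------------------------- sizing

struct Sizing {
  // segments: ax ay az bx by bz ra rb (radii at the two endpoints)
  int nseg = 0;
  std::vector<double> ax, ay, az, ux, uy, uz, len, ra, rb;
  // separating points: x y z l_min rho
  int nsep = 0;
  std::vector<double> px_, py_, pz_, slmin, srho;
  double l_soma = 1, soma_radius = 1, l_floor = 0, l_cap = 1;
  double dband = 0, lT = std::numeric_limits<double>::infinity();

  void build(List sz) {
    NumericMatrix S = sz["segments"], P = sz["separating"];
    l_soma = as<double>(sz["l_soma"]);
    soma_radius = as<double>(sz["soma_radius"]);
    l_floor = as<double>(sz["l_floor"]);
    l_cap = as<double>(sz["l_cap"]);
    if (sz.containsElementNamed("d")) dband = as<double>(sz["d"]);
    else dband = 0.5 * l_floor;
    if (sz.containsElementNamed("l_T")) lT = as<double>(sz["l_T"]);
    nseg = S.nrow();
    ax.resize(nseg); ay.resize(nseg); az.resize(nseg);
    ux.resize(nseg); uy.resize(nseg); uz.resize(nseg);
    len.resize(nseg); ra.resize(nseg); rb.resize(nseg);
    for (int i = 0; i < nseg; ++i) {
      ax[i]=S(i,0); ay[i]=S(i,1); az[i]=S(i,2);
      double dx=S(i,3)-S(i,0), dy=S(i,4)-S(i,1), dz=S(i,5)-S(i,2);
      len[i] = std::sqrt(dx*dx+dy*dy+dz*dz);
      if (len[i] > 0) { ux[i]=dx/len[i]; uy[i]=dy/len[i]; uz[i]=dz/len[i]; }
      else { ux[i]=uy[i]=uz[i]=0; }
      ra[i]=S(i,6); rb[i]=S(i,7);
    }
    nsep = P.nrow();
    px_.resize(nsep); py_.resize(nsep); pz_.resize(nsep);
    slmin.resize(nsep); srho.resize(nsep);
    for (int i = 0; i < nsep; ++i) {
      px_[i]=P(i,0); py_[i]=P(i,1); pz_[i]=P(i,2); slmin[i]=P(i,3); srho[i]=P(i,4);
    }
  }

  // local skeleton radius: radius linearly interpolated along the nearest segment
  double local_radius(double x, double y, double z) const {
    double best = std::numeric_limits<double>::infinity(), r = soma_radius;
    for (int i = 0; i < nseg; ++i) {
      double px = x-ax[i], py = y-ay[i], pz = z-az[i];
      double t = len[i] > 0 ? std::max(0.0, std::min(len[i], px*ux[i]+py*uy[i]+pz*uz[i])) : 0.0;
      double cx = px - t*ux[i], cy = py - t*uy[i], cz = pz - t*uz[i];
      double d2 = cx*cx + cy*cy + cz*cz;
      if (d2 < best) {
        best = d2;
        double w = len[i] > 0 ? t / len[i] : 0.0;
        r = ra[i] + w * (rb[i] - ra[i]);
      }
    }
    return r;
  }
  double l_max(double x, double y, double z) const {
    double l = l_soma * local_radius(x, y, z) / soma_radius;
    return std::max(l_floor, std::min(l_cap, l));
  }
  double target(double x, double y, double z) const {
    double lmax = l_max(x, y, z), t = lmax;
    for (int i = 0; i < nsep; ++i) {
      double dx = x-px_[i], dy = y-py_[i], dz = z-pz_[i];
      double dist = std::sqrt(dx*dx+dy*dy+dz*dz);
      if (dist < srho[i]) {
        double w = 1.0 - dist / srho[i];
        double l = (1.0 - w) * lmax + w * std::max(slmin[i], l_floor);
        if (l < t) t = l;
      }
    }
    return std::max(l_floor, std::min(l_cap, t));
  }
};

// [[Rcpp::export]]
NumericVector sz_target(List sizing, NumericMatrix P) {
  Sizing s; s.build(sizing);
  NumericVector out(P.nrow());
  for (int i = 0; i < P.nrow(); ++i) out[i] = s.target(P(i,0), P(i,1), P(i,2));
  return out;
}

// [[Rcpp::export]]
NumericVector sz_local_max(List sizing, NumericMatrix P) {
  Sizing s; s.build(sizing);
  NumericVector out(P.nrow());
  for (int i = 0; i < P.nrow(); ++i) out[i] = s.l_max(P(i,0), P(i,1), P(i,2));
  return out;
}

// ------------------------------------------------------------- remeshing

struct RegionFlags {
  std::vector<char> in;
  std::vector<int> verts; // members (possibly stale; callers check valive)
  void ensure(int n) { if ((int)in.size() < n) in.resize(n, 0); }
  bool has(int v) const { return v < (int)in.size() && in[v]; }
  void add(int v) {
    ensure(v + 1);
    if (!in[v]) { in[v] = 1; verts.push_back(v); }
  }
};

static double edge_target(const Sizing& sz, const HEMesh* m, int h) {
  int a = m->horig[h], b = m->head(h);
  double mx = 0.5*(m->vx[a] + m->vx[b]);
  double my = 0.5*(m->vy[a] + m->vy[b]);
  double mz = 0.5*(m->vz[a] + m->vz[b]);
  return sz.target(mx, my, mz);
}

// canonical edges with at least one endpoint in the region, gathered from
// the region vertices' fans (O(region), not O(mesh))
static void region_edges(const HEMesh* m, const RegionFlags& reg, std::vector<int>& out) {
  out.clear();
  for (int v : reg.verts) {
    if (v >= m->n_vslots() || !m->valive[v] || !reg.has(v)) continue;
    int h0 = m->vhe[v], hh = h0;
    if (h0 < 0) continue;
    int guard = m->n_hslots() + 1;
    do {
      out.push_back(m->canon(hh));
      int t = m->htwin[hh];
      if (t < 0) break;
      hh = m->hnext[t];
    } while (hh != h0 && --guard > 0);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

// longest-edge-first split queue: splitting the longest edge first keeps
// the incident triangles from degenerating into needles whose cross edges
// would re-feed the queue indefinitely
static int pass_split(SEXP xp, HEMesh* m, const Sizing& sz, RegionFlags& reg, double beta) {
  std::vector<int> q;
  region_edges(m, reg, q);
  typedef std::pair<double, int> LE;
  std::priority_queue<LE> queue;
  for (int h : q) {
    double len = m->dist(m->horig[h], m->head(h));
    queue.push(LE(len, h));
  }
  int edits = 0;
  const int cap = 500000; // safety valve; later passes resume if ever hit
  while (!queue.empty() && edits < cap) {
    LE top = queue.top(); queue.pop();
    int h = top.second;
    if (h >= m->n_hslots() || !m->halive[h]) continue;
    int a = m->horig[h], b = m->head(h);
    if (!(reg.has(a) || reg.has(b))) continue;
    double len = m->dist(a, b);
    if (len != top.first) continue; // stale entry; edge was rewritten
    if (len <= beta * edge_target(sz, m, h)) continue;
    // progress rule: in a needle triangle the midpoint's cross edge can be
    // as long as the split edge itself, re-feeding the queue forever;
    // refuse such splits (the collapse pass removes the needle instead)
    {
      int t = m->htwin[h];
      int c = m->horig[m->hnext[m->hnext[h]]];
      int d = m->horig[m->hnext[m->hnext[t]]];
      double mx = 0.5*(m->vx[a]+m->vx[b]);
      double my = 0.5*(m->vy[a]+m->vy[b]);
      double mz = 0.5*(m->vz[a]+m->vz[b]);
      double cx = m->vx[c]-mx, cy = m->vy[c]-my, cz = m->vz[c]-mz;
      double dx = m->vx[d]-mx, dy = m->vy[d]-my, dz = m->vz[d]-mz;
      double lc = std::sqrt(cx*cx+cy*cy+cz*cz);
      double ld = std::sqrt(dx*dx+dy*dy+dz*dz);
      if (lc > 0.95 * len || ld > 0.95 * len) continue;
    }
    int mv = he_split_edge(xp, h + 1) - 1;
    reg.add(mv);
    ++edits;
    // enqueue the edges incident to the new vertex
    int h0 = m->vhe[mv], hh = h0;
    int guard = m->n_hslots() + 1;
    do {
      int c = m->canon(hh);
      queue.push(LE(m->dist(m->horig[c], m->head(c)), c));
      hh = m->hnext[m->htwin[hh]];
    } while (hh != h0 && --guard > 0);
  }
  return edits;
}

// would collapsing edge h create an edge longer than `bound` around the
// midpoint?
static bool collapse_makes_long(const HEMesh* m, int h, double bound) {
  int a = m->horig[h], b = m->head(h);
  double mx = 0.5*(m->vx[a]+m->vx[b]), my = 0.5*(m->vy[a]+m->vy[b]), mz = 0.5*(m->vz[a]+m->vz[b]);
  std::vector<int> ra, rb;
  if (!m->one_ring(a, ra) || !m->one_ring(b, rb)) return true;
  for (int pass = 0; pass < 2; ++pass) {
    const std::vector<int>& ring = pass == 0 ? ra : rb;
    for (int u : ring) {
      if (u == a || u == b) continue;
      double dx = m->vx[u]-mx, dy = m->vy[u]-my, dz = m->vz[u]-mz;
      if (std::sqrt(dx*dx+dy*dy+dz*dz) > bound) return true;
    }
  }
  return false;
}

static int pass_collapse(SEXP xp, HEMesh* m, const Sizing& sz, RegionFlags& reg,
                         double alpha, double beta) {
  int total = 0;
  for (int round = 0; round < 5; ++round) {
    std::vector<int> q;
    region_edges(m, reg, q);
    int edits = 0;
    for (int h : q) {
      if (h >= m->n_hslots() || !m->halive[h]) continue;
      int a = m->horig[h], b = m->head(h);
      if (!(reg.has(a) || reg.has(b))) continue;
      double len = m->dist(a, b);
      double t = edge_target(sz, m, h);
      if (len >= alpha * t) continue;
      // edges below the global band floor must go even if that creates an
      // edge above the local threshold; the global cap still holds and the
      // split pass re-balances
      bool desperate = len < sz.dband;
      double bound = desperate ? std::max(beta * t, sz.lT) : beta * t;
      if (!collapse_makes_long(m, h, bound)) {
        // for sub-floor needles inside crumpled folds the normal-flip
        // surrogate is meaningless; the link condition alone guards topology
        int surv = he_collapse_edge(xp, h + 1, desperate);
        if (surv > 0) { reg.add(surv - 1); ++edits; continue; }
      }
      if (!desperate) continue;
      double bigbound = std::max(beta * t, sz.lT);
      // link-illegal or over-long: retire the needle by collapsing one of
      // the sibling edges of its two incident triangles instead
      bool fixed = false;
      int t2 = m->htwin[h];
      int sib[4] = { m->hnext[h], m->hnext[m->hnext[h]],
                     m->hnext[t2], m->hnext[m->hnext[t2]] };
      for (int k = 0; k < 4; ++k) {
        int hs = sib[k];
        if (!m->halive[hs]) continue;
        if (collapse_makes_long(m, hs, bigbound)) continue;
        int surv = he_collapse_edge(xp, hs + 1, true);
        if (surv > 0) { reg.add(surv - 1); ++edits; fixed = true; break; }
      }
      if (fixed) continue;
      // still stuck (usually an extra common one-ring neighbour blocking
      // the link condition): try flipping an incident edge to unlock the
      // collapse, undoing any flip that does not help
      std::vector<int> fan;
      for (int end = 0; end < 2 && !fixed; ++end) {
        int v = end == 0 ? a : b;
        fan.clear();
        int h0 = m->vhe[v], hh = h0;
        int guard = m->n_hslots() + 1;
        do {
          int c = m->canon(hh);
          if (c != m->canon(h)) fan.push_back(c);
          int tt = m->htwin[hh];
          if (tt < 0) break;
          hh = m->hnext[tt];
        } while (hh != h0 && --guard > 0);
        for (int fe : fan) {
          if (fe >= m->n_hslots() || !m->halive[fe]) continue;
          if (!he_flip_edge(xp, fe + 1)) continue;
          if (!m->halive[h]) { fixed = true; break; } // edge gone via flip? cannot happen, safety
          if (!collapse_makes_long(m, h, bigbound)) {
            int surv = he_collapse_edge(xp, h + 1, true);
            if (surv > 0) { reg.add(surv - 1); ++edits; fixed = true; break; }
          }
          he_flip_edge(xp, fe + 1); // undo
        }
      }
      if (fixed) continue;
      // final fallback: the guard fails because a ring vertex sits almost
      // a full band-cap away; splitting those long incident edges brings
      // the ring in, after which the collapse is safe
      for (int end = 0; end < 2; ++end) {
        int v = end == 0 ? a : b;
        if (!m->valive[v]) break;
        std::vector<int> ring;
        if (!m->one_ring(v, ring)) continue;
        double mx = 0.5*(m->vx[a]+m->vx[b]), my = 0.5*(m->vy[a]+m->vy[b]), mz = 0.5*(m->vz[a]+m->vz[b]);
        for (int u : ring) {
          if (u == a || u == b) continue;
          double dx = m->vx[u]-mx, dy = m->vy[u]-my, dz = m->vz[u]-mz;
          if (std::sqrt(dx*dx+dy*dy+dz*dz) <= bigbound) continue;
          int fe = -1;
          {
            int h0 = m->vhe[v], hh = h0;
            int guard = m->n_hslots() + 1;
            do {
              if (m->head(hh) == u) { fe = m->canon(hh); break; }
              int tt = m->htwin[hh];
              if (tt < 0) break;
              hh = m->hnext[tt];
            } while (hh != h0 && --guard > 0);
          }
          if (fe < 0) continue;
          int mv = he_split_edge(xp, fe + 1) - 1;
          reg.add(mv);
        }
      }
      if (m->halive[h] && !collapse_makes_long(m, h, bigbound)) {
        int surv = he_collapse_edge(xp, h + 1, true);
        if (surv > 0) { reg.add(surv - 1); ++edits; }
      }
    }
    total += edits;
    if (edits == 0) break;
  }
  return total;
}

static int pass_equalize(SEXP xp, HEMesh* m, RegionFlags& reg) {
  std::vector<int> q;
  region_edges(m, reg, q);
  int edits = 0;
  for (int h : q) {
    if (h >= m->n_hslots() || !m->halive[h]) continue;
    int t = m->htwin[h];
    if (t < 0) continue;
    int a = m->horig[h], b = m->horig[t];
    int c = m->horig[m->hnext[m->hnext[h]]];
    int d = m->horig[m->hnext[m->hnext[t]]];
    int va = m->valence(a), vb = m->valence(b), vc = m->valence(c), vd = m->valence(d);
    if (va < 0 || vb < 0 || vc < 0 || vd < 0) continue;
    auto dev = [](int v) { return (v - 6) * (v - 6); };
    int before = dev(va) + dev(vb) + dev(vc) + dev(vd);
    int after = dev(va - 1) + dev(vb - 1) + dev(vc + 1) + dev(vd + 1);
    if (after >= before) continue;
    if (he_flip_edge(xp, h + 1)) ++edits;
  }
  return edits;
}

// area-based tangential relaxation (Jacobi snapshot), then damped
// tangent-plane move
static int pass_relax(HEMesh* m, const RegionFlags& reg, double lambda_damp) {
  // live region vertices and the faces within two rings of them (the
  // neighbours' barycentric areas are needed)
  std::vector<int> live;
  for (int v : reg.verts)
    if (v < m->n_vslots() && m->valive[v] && reg.has(v)) live.push_back(v);
  std::sort(live.begin(), live.end());
  live.erase(std::unique(live.begin(), live.end()), live.end());

  std::vector<int> ring, need = live, faces;
  for (int v : live) {
    if (!m->one_ring(v, ring)) continue;
    need.insert(need.end(), ring.begin(), ring.end());
  }
  std::sort(need.begin(), need.end());
  need.erase(std::unique(need.begin(), need.end()), need.end());
  for (int v : need) {
    int h0 = m->vhe[v], hh = h0;
    if (h0 < 0) continue;
    int guard = m->n_hslots() + 1;
    do {
      faces.push_back(m->hface[hh]);
      int t = m->htwin[hh];
      if (t < 0) break;
      hh = m->hnext[t];
    } while (hh != h0 && --guard > 0);
  }
  std::sort(faces.begin(), faces.end());
  faces.erase(std::unique(faces.begin(), faces.end()), faces.end());

  // barycentric (one-third) vertex areas and area-weighted vertex normals
  int nv = m->n_vslots();
  std::vector<double> area(nv, 0.0), nxv(nv, 0.0), nyv(nv, 0.0), nzv(nv, 0.0);
  for (int f : faces) {
    if (f < 0 || !m->falive[f]) continue;
    int vv[3]; m->face_verts(f, vv);
    double n[3]; m->face_normal(f, n);
    double a2 = 0.5 * std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
    for (int k = 0; k < 3; ++k) {
      area[vv[k]] += a2 / 3.0;
      nxv[vv[k]] += n[0]; nyv[vv[k]] += n[1]; nzv[vv[k]] += n[2];
    }
  }
  // snapshot of the positions that the barycenters read
  const std::vector<double>& px = m->vx;
  const std::vector<double>& py = m->vy;
  const std::vector<double>& pz = m->vz;
  std::vector<double> sx(live.size()), sy(live.size()), sz2(live.size());
  std::vector<char> do_move(live.size(), 0);
  int moved = 0;
  for (size_t li = 0; li < live.size(); ++li) {
    int v = live[li];
    if (!m->one_ring(v, ring)) continue;
    double wsum = 0, gx = 0, gy = 0, gz = 0;
    for (int u : ring) {
      double w = area[u];
      wsum += w;
      gx += w * px[u]; gy += w * py[u]; gz += w * pz[u];
    }
    if (wsum <= 0) continue; // zero total neighbour area: leave in place
    gx /= wsum; gy /= wsum; gz /= wsum;
    double nx = nxv[v], ny = nyv[v], nz = nzv[v];
    double nn = std::sqrt(nx*nx + ny*ny + nz*nz);
    if (nn < 1e-300) continue;
    nx /= nn; ny /= nn; nz /= nn;
    double dx = gx - px[v], dy = gy - py[v], dz = gz - pz[v];
    double dn = dx*nx + dy*ny + dz*nz;
    double mx = lambda_damp * (dx - dn*nx);
    double my = lambda_damp * (dy - dn*ny);
    double mz = lambda_damp * (dz - dn*nz);
    if (mx != 0 || my != 0 || mz != 0) ++moved;
    // deferred write keeps the pass Jacobi (order-independent)
    sx[li] = px[v] + mx; sy[li] = py[v] + my; sz2[li] = pz[v] + mz;
    do_move[li] = 1;
  }
  for (size_t li = 0; li < live.size(); ++li) {
    if (!do_move[li]) continue;
    int v = live[li];
    m->vx[v] = sx[li]; m->vy[v] = sy[li]; m->vz[v] = sz2[li];
  }
  return moved;
}

static void pass_project(HEMesh* m, const RegionFlags& reg, const Sources& s,
                         double T, double tol, int maxit, double h,
                         bool gate_unbound, int* projected, int* nonconv) {
  std::vector<int> ring;
  *projected = 0; *nonconv = 0;
  std::vector<int> live(reg.verts);
  std::sort(live.begin(), live.end());
  live.erase(std::unique(live.begin(), live.end()), live.end());
  for (int v : live) {
    if (v >= m->n_vslots() || !m->valive[v] || !reg.has(v)) continue;
    // only vertices inside some support capsule can be projected
    bool inside = false;
    const std::vector<int>* cand = s.candidates(m->vx[v], m->vy[v], m->vz[v]);
    if (cand)
      for (int k : *cand)
        if (s.dist2(k, m->vx[v], m->vy[v], m->vz[v]) < s.R[k]*s.R[k]) { inside = true; break; }
    if (!inside) continue;
    // a vertex engages the iso-surface from inside (F > T pushes it out);
    // once it has reached the surface it stays bound and tracks it in both
    // directions. Sub-threshold, never-bound vertices (e.g. the far soma
    // sphere) are left in place -- the field only adds material there.
    if (gate_unbound && !m->vbound[v]) {
      double F = field_at(s, m->vx[v], m->vy[v], m->vz[v], false);
      if (F <= T) continue;
    }
    if (!m->one_ring(v, ring)) continue;
    double le = std::numeric_limits<double>::infinity();
    for (int u : ring) le = std::min(le, m->dist(v, u));
    double p[3] = { m->vx[v], m->vy[v], m->vz[v] };
    int it = 0;
    bool ok = project_one(s, T, tol, maxit, 0.5 * le, h, p, &it);
    m->vx[v] = p[0]; m->vy[v] = p[1]; m->vz[v] = p[2];
    ++*projected;
    if (ok) m->vbound[v] = 1;
    else ++*nonconv;
  }
}

// [[Rcpp::export]]
LogicalVector he_bound(SEXP xp, IntegerVector vids) {
  HEMesh* m = get_mesh(xp);
  LogicalVector out(vids.size());
  for (int i = 0; i < vids.size(); ++i) {
    int v = vids[i] - 1;
    check_vertex_handle(m, v);
    out[i] = m->vbound[v] != 0;
  }
  return out;
}

// [[Rcpp::export]]
List rm_remesh_region(SEXP xp, IntegerVector region, List sizing, NumericMatrix S,
                      double alpha, double beta, double lambda_damp, int iters,
                      double iso, double tol, int maxit, bool do_project = true,
                      Nullable<LogicalVector> enable = R_NilValue,
                      bool gate_unbound = false) {
  HEMesh* m = get_mesh(xp);
  Sizing sz; sz.build(sizing);
  Sources src; src.build(S);
  double h = 1e-4 * src.mind;
  bool en[4] = { true, true, true, true }; // split, collapse, equalize, relax
  if (enable.isNotNull()) {
    LogicalVector e(enable);
    if (e.size() != 4) stop("enable must have 4 entries");
    for (int k = 0; k < 4; ++k) en[k] = e[k];
  }
  RegionFlags reg;
  reg.ensure(m->n_vslots());
  for (int i = 0; i < region.size(); ++i) {
    int v = region[i] - 1;
    check_vertex_handle(m, v);
    reg.add(v);
  }
  int splits = 0, collapses = 0, flips = 0, moved = 0, projected = 0, nonconv = 0;
  for (int it = 0; it < iters; ++it) {
    if (en[0]) splits += pass_split(xp, m, sz, reg, beta);
    if (en[1]) collapses += pass_collapse(xp, m, sz, reg, alpha, beta);
    if (en[2]) flips += pass_equalize(xp, m, reg);
    if (en[3]) moved += pass_relax(m, reg, lambda_damp);
    if (do_project && src.n > 0) {
      int pr = 0, nc = 0;
      pass_project(m, reg, src, iso, tol, maxit, h, gate_unbound, &pr, &nc);
      projected += pr; nonconv = nc; // last pass's count is the meaningful one
    }
  }
  std::vector<int> out;
  for (int v = 0; v < (int)reg.in.size(); ++v)
    if (reg.in[v] && v < m->n_vslots() && m->valive[v]) out.push_back(v + 1);
  return List::create(
    _["splits"] = splits, _["collapses"] = collapses, _["flips"] = flips,
    _["relaxed"] = moved, _["projected"] = projected,
    _["non_converged"] = nonconv, _["region"] = wrap(out));
}

// project an explicit vertex set of the mesh onto the field (deform step)
// [[Rcpp::export]]
List rm_project_vertices(SEXP xp, IntegerVector vids, NumericMatrix S,
                         double iso, double tol, int maxit,
                         bool gate_unbound = false) {
  HEMesh* m = get_mesh(xp);
  Sources src; src.build(S);
  double h = 1e-4 * src.mind;
  RegionFlags reg;
  reg.ensure(m->n_vslots());
  for (int i = 0; i < vids.size(); ++i) {
    int v = vids[i] - 1;
    check_vertex_handle(m, v);
    reg.add(v);
  }
  int projected = 0, nonconv = 0;
  if (src.n > 0) pass_project(m, reg, src, iso, tol, maxit, h, gate_unbound, &projected, &nonconv);
  return List::create(_["projected"] = projected, _["non_converged"] = nonconv);
}

// ------------------------------------------------- skeletal mapping helpers

// assign owners: nearest endpoint node of the segment holding the closest
// projection among active segments; ties go to the lower node id.
// segs: ax ay az bx by bz ida idb
// [[Rcpp::export]]
IntegerVector sv_assign(SEXP xp, IntegerVector vids, NumericMatrix segs) {
  HEMesh* m = get_mesh(xp);
  if (segs.nrow() == 0) stop("no active segments");
  IntegerVector out(vids.size());
  int ns = segs.nrow();
  std::vector<double> ax(ns), ay(ns), az(ns), ux(ns), uy(ns), uz(ns), len(ns);
  for (int i = 0; i < ns; ++i) {
    ax[i]=segs(i,0); ay[i]=segs(i,1); az[i]=segs(i,2);
    double dx=segs(i,3)-ax[i], dy=segs(i,4)-ay[i], dz=segs(i,5)-az[i];
    len[i] = std::sqrt(dx*dx+dy*dy+dz*dz);
    if (len[i] > 0) { ux[i]=dx/len[i]; uy[i]=dy/len[i]; uz[i]=dz/len[i]; }
    else { ux[i]=uy[i]=uz[i]=0; }
  }
  for (int j = 0; j < vids.size(); ++j) {
    int v = vids[j] - 1;
    check_vertex_handle(m, v);
    double x = m->vx[v], y = m->vy[v], z = m->vz[v];
    double best = std::numeric_limits<double>::infinity();
    int owner = 0;
    for (int i = 0; i < ns; ++i) {
      double px = x-ax[i], py = y-ay[i], pz = z-az[i];
      double t = len[i] > 0 ? std::max(0.0, std::min(len[i], px*ux[i]+py*uy[i]+pz*uz[i])) : 0.0;
      double cx = px - t*ux[i], cy = py - t*uy[i], cz = pz - t*uz[i];
      double d2 = cx*cx + cy*cy + cz*cz;
      int ida = (int)segs(i,6), idb = (int)segs(i,7);
      // endpoint of this segment nearest the projection position
      int node;
      double half = 0.5 * len[i];
      if (t < half) node = ida;
      else if (t > half) node = idb;
      else node = std::min(ida, idb); // equidistant: lower node id wins
      const double eps = 1e-12 * (1.0 + best);
      if (owner == 0 || d2 < best - eps) { best = d2; owner = node; }
      else if (d2 <= best + eps) owner = std::min(owner, node);
    }
    m->vowner[v] = owner;
    out[j] = owner;
  }
  return out;
}

// ROI query: vertices within `radius` of the query position. The mapped
// route prefilters by owning-node distance (radius + slack bounds the
// vertex-to-owner distance); brute force scans every live vertex. Both
// return identical sets.
// [[Rcpp::export]]
IntegerVector sv_roi(SEXP xp, NumericVector q, double radius,
                     NumericMatrix node_pos, IntegerVector node_ids,
                     double slack, bool brute = false) {
  HEMesh* m = get_mesh(xp);
  double r2 = radius * radius;
  std::vector<int> out;
  if (brute) {
    for (int v = 0; v < m->n_vslots(); ++v) {
      if (!m->valive[v]) continue;
      double dx = m->vx[v]-q[0], dy = m->vy[v]-q[1], dz = m->vz[v]-q[2];
      if (dx*dx + dy*dy + dz*dz <= r2) out.push_back(v + 1);
    }
    return wrap(out);
  }
  double rs = (radius + slack) * (radius + slack);
  std::unordered_map<int, char> near_nodes;
  for (int i = 0; i < node_pos.nrow(); ++i) {
    double dx = node_pos(i,0)-q[0], dy = node_pos(i,1)-q[1], dz = node_pos(i,2)-q[2];
    if (dx*dx + dy*dy + dz*dz <= rs) near_nodes[node_ids[i]] = 1;
  }
  for (int v = 0; v < m->n_vslots(); ++v) {
    if (!m->valive[v]) continue;
    if (!near_nodes.count(m->vowner[v])) continue;
    double dx = m->vx[v]-q[0], dy = m->vy[v]-q[1], dz = m->vz[v]-q[2];
    if (dx*dx + dy*dy + dz*dz <= r2) out.push_back(v + 1);
  }
  return wrap(out);
}
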