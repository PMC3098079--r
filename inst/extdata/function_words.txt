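# Function word list v1: articles, determiners, prepositions, conjunctions,
# pronouns, auxiliaries/modals, and degree/negation particles.
a
an
the
this
that
these
those
some
any
each
every
either
neither
both
all
few
many
much
more
most
several
such
no
another
other
same
own
in
on
at
by
for
with
about
against
between
among
into
through
during
before
after
above
below
to
from
up
down
of
off
over
under
again
further
then
once
here
there
when
where
why
how
what
which
who
whom
whose
as
until
while
because
although
though
since
unless
whereas
whether
if
than
and
or
but
nor
so
yet
not
only
also
just
very
too
quite
rather
almost
even
still
already
ever
never
always
often
sometimes
usually
i
me
my
mine
myself
we
us
our
ours
ourselves
you
your
yours
yourself
he
him
his
himself
she
her
hers
herself
it
its
itself
they
them
their
theirs
themselves
one
ones
be
am
is
are
was
were
been
being
have
has
had
having
do
does
did
doing
will
would
shall
should
may
might
must
can
could
ought
need
dare
per
via
upon
within
without
toward
towards
onto
across
along
around
behind
beneath
beside
besides
beyond
despite
except
inside
outside
near
past
throughout
underneath
unlike
versus
vs
amid
amidst
whereby
wherein
thus
hence
therefore
however
moreover
furthermore
nevertheless
nonetheless
meanwhile
otherwise
instead
indeed
perhaps
respectively
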