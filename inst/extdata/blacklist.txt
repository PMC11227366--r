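# Default blacklist: standard English stop words, auxiliary/copular verbs,
# and conjunctions. Removed from term surfaces at indexing time and treated
# as transparent (non-breaking, non-matching) inside text candidates.
# stop words
a
an
the
of
in
on
at
to
from
by
for
with
without
within
into
onto
upon
about
above
below
over
under
between
among
through
during
before
after
against
as
per
via
off
out
up
down
this
that
these
those
it
its
their
his
her
them
they
he
she
we
you
i
me
my
our
your
us
than
then
there
here
where
when
which
who
whom
whose
what
while
if
because
so
such
not
no
nor
only
also
both
each
either
neither
any
some
all
more
most
other
own
same
too
very
# auxiliary and copular verbs
be
is
are
am
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
can
could
may
might
must
# conjunctions
and
or
but
yet
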