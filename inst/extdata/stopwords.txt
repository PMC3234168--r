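# Built-in English stop list: articles, prepositions, conjunctions,
# pronouns, auxiliaries and light verbs without domain-specific meaning.
# One word per line; '#' starts a comment.  Deliberately excludes
# content-bearing words a combat-exposure lexicon may need (see, stop,
# fire, hit, ...).
a
about
above
across
after
again
against
all
almost
also
although
am
an
and
any
anyone
anything
are
around
as
at
be
became
because
become
been
before
being
below
between
both
but
by
came
can
cannot
come
could
did
do
does
doing
done
down
during
each
either
else
even
ever
every
few
for
from
further
gave
get
gets
getting
give
given
go
goes
going
gone
got
had
has
have
having
he
her
here
hers
herself
him
himself
his
how
however
i
if
in
into
is
it
its
itself
just
least
less
let
like
made
make
makes
many
may
me
might
more
most
much
must
my
myself
neither
never
no
nor
not
now
of
off
often
on
once
one
only
onto
or
other
our
ours
ourselves
out
over
own
per
perhaps
put
quite
rather
same
she
should
since
so
some
someone
something
still
such
take
than
that
the
their
theirs
them
themselves
then
there
these
they
this
those
though
through
to
too
took
toward
under
until
unto
up
upon
us
very
was
we
went
were
what
when
where
whether
which
while
who
whom
whose
why
will
with
within
without
would
yet
you
your
yours
yourself
yourselves
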