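# General-English filter wordlist v1 (common-word frequency list,
# curated; one lower-case word per line). A configurable input to
# filter_dictionary(); substitute any larger frequency list.
a
able
about
above
account
across
act
action
after
again
against
ago
aid
air
all
almost
alone
along
already
also
although
always
american
among
amount
an
and
another
any
anything
are
area
army
around
as
asked
at
available
away
back
basic
basis
be
became
because
become
been
before
began
behind
being
believe
best
better
between
big
black
blood
board
body
born
both
boy
bring
brought
building
business
but
by
called
came
can
cannot
car
case
century
certain
certainly
change
children
church
city
class
clear
close
cold
college
come
committee
common
company
complete
control
cost
could
council
country
course
cut
date
day
deal
death
development
did
didn
different
difficult
direction
do
does
don
done
door
doubt
down
due
during
each
early
education
effect
either
end
enough
even
ever
every
evidence
example
experience
eyes
face
fact
family
far
feel
feet
felt
few
field
figure
find
fine
fire
first
five
food
for
force
form
former
found
four
france
free
from
front
future
gave
general
get
girl
give
given
go
god
going
gone
good
got
government
great
ground
group
had
half
hand
happened
has
have
having
he
head
heard
held
help
her
here
high
him
himself
his
history
hold
home
hope
hot
hours
house
how
however
human
hundred
i
idea
if
important
in
including
increase
individual
instead
interest
into
is
it
its
itself
job
just
keep
kept
kind
knew
know
land
large
last
late
later
law
lay
lead
least
left
less
let
level
life
light
like
line
list
little
local
long
longer
look
looked
lost
love
low
made
major
make
making
man
many
market
material
matter
may
me
means
members
men
met
method
might
miles
military
mind
minutes
modern
moment
money
more
morning
most
mother
moved
mr
mrs
much
must
my
name
nation
national
nature
near
nearly
need
needed
never
new
next
night
no
not
note
nothing
now
number
of
off
office
often
old
on
once
one
only
open
or
order
other
others
our
out
over
own
paper
part
particular
party
past
pay
people
per
performance
perhaps
period
person
picture
piece
place
plan
play
point
policy
political
position
possible
power
present
president
pressure
private
problem
program
provide
provided
public
purpose
put
question
quite
range
rate
rather
read
ready
real
really
reason
received
red
report
required
rest
result
return
right
road
room
run
said
same
saw
say
school
second
section
see
seem
seems
seen
sense
service
set
several
she
short
should
show
shown
side
simply
since
single
situation
six
size
small
so
social
society
some
something
sometimes
son
sort
sound
south
space
special
stage
start
state
states
still
stock
stood
stop
story
street
strength
student
study
such
system
table
take
taken
taking
ten
than
the
their
them
themselves
then
there
therefore
these
they
thing
things
third
this
those
though
thought
three
through
thus
time
times
to
today
told
too
took
total
toward
town
trade
tried
turn
turned
two
type
under
united
until
up
upon
us
use
used
usually
value
various
very
view
voice
want
wanted
war
was
water
way
we
week
well
went
were
what
when
where
whether
which
while
white
who
whole
whose
why
wife
will
with
within
without
word
words
work
working
world
would
wrong
year
years
yes
yet
you
young
your
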